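test_that("baseline is the mean of the closed 150-200 ms window", {
  expect_equal(baseline_size(make_trace(rep(5, 400)), fp_on = 0), 5)
  # linear ramp 4 mm at 150 ms to 4.1 mm at 200 ms: mean is the midpoint
  t <- seq(0, 798, by = 2)
  p <- 4 + (t - 150) / 50 * 0.1
  expect_equal(baseline_size(make_trace(p), fp_on = 0), 4.05)
  # the closed window holds 26 samples at 500 Hz (independent count)
  expect_equal(sum(t >= 150 & t <= 200), 26)
  # any invalid sample inside the window undefines the measure
  v <- rep(TRUE, 400); v[88] <- FALSE  # t = 174 ms
  expect_true(is.na(baseline_size(make_trace(rep(5, 400), valid = v), 0)))
})

test_that("baseline correction zeroes the baseline window and is idempotent", {
  tr <- make_trace(rep(5, 400))
  z <- baseline_correct(tr, 5)
  expect_true(all(z$pupil == 0))
  b2 <- baseline_size(z, 0)
  expect_lt(abs(b2), 1e-12)
  expect_equal(baseline_correct(z, b2)$pupil, z$pupil)
})

test_that("pupil velocity is exact on constants and ramps, accurate on sines", {
  expect_true(all(pupil_velocity(make_trace(rep(5, 100))) == 0))
  t_s <- seq(0, 1.998, by = 0.002)
  ramp <- make_trace(5 + 0.8 * t_s)
  v <- pupil_velocity(ramp)
  expect_equal(v[2:999], rep(0.8, 998), tolerance = 1e-9)
  f <- 2  # Hz
  sine <- make_trace(5 + 0.3 * sin(2 * pi * f * t_s))
  vmax <- max(abs(pupil_velocity(sine)), na.rm = TRUE)
  expect_equal(vmax, 0.3 * 2 * pi * f, tolerance = 0.01)
})

test_that("onset latency finds the start of the velocity departure", {
  cc <- noiseless_config()
  trace <- generate_trial_trace(
    make_trial(constriction_latency_ms = 450, constriction_peak_ms = 1000),
    cc)
  ol <- onset_latency(trace, fp_on = 0, stim_on = 1200)
  expect_true(abs(ol - 450) <= 20)
  flat <- make_trace(rep(5, 1600))
  expect_true(is.na(onset_latency(flat, 0, 1200)))
})

test_that("constriction features recover the planted minimum", {
  cc <- noiseless_config()
  trace <- generate_trial_trace(make_trial(), cc)
  b <- baseline_size(trace, 0)
  cf <- constriction_features(trace, 0, 1200, b)
  expect_equal(cf$constriction_size, 0.4, tolerance = 1e-9)
  expect_equal(cf$peak_constriction_time, 900)
  expect_lte(cf$peak_constriction_velocity, 0)
  # analytic minimum velocity of the half-cosine pulse
  expect_equal(cf$peak_constriction_velocity, -0.4 * pi / (2 * 0.65),
               tolerance = 0.001)
  expect_false(cf$degenerate)
  # constant trace: zero-size constriction flagged degenerate
  const <- constriction_features(make_trace(rep(5, 1600)), 0, 1200, 5)
  expect_equal(const$constriction_size, 0)
  expect_equal(const$peak_constriction_velocity, 0)
  expect_true(const$degenerate)
})

test_that("dilation features match the closed-form ramp values", {
  cc <- noiseless_config()
  trace <- generate_trial_trace(make_trial(), cc)
  df <- dilation_features(trace, peak_time = 900, fp_on = 0, stim_on = 1200)
  # ramp 0.8 mm/s from the peak: window mean sits at stim_on - 25 ms
  expect_equal(df$dilation_size, 0.8 * (1175 - 900) / 1000, tolerance = 1e-9)
  expect_equal(df$dilation_velocity, 0.8, tolerance = 1e-9)
  expect_equal(df$peak_dilation_velocity, 0.8, tolerance = 1e-9)
  # flat trace: all three zero
  flat <- dilation_features(make_trace(rep(5, 1600)), 900, 0, 1200)
  expect_equal(flat$dilation_size, 0)
  expect_equal(flat$dilation_velocity, 0)
  expect_equal(flat$peak_dilation_velocity, 0)
  # peak too close to stimulus onset is degenerate
  late <- dilation_features(trace, peak_time = 1160, fp_on = 0,
                            stim_on = 1200)
  expect_true(late$degenerate)
})

test_that("peak dilation velocity dominates the window-mean velocity", {
  cc <- cohort_config(n_participants = 1, seed = 10, noise_sd = 0.02,
                      blink_rate = 0)
  for (s in 1:10) {
    trace <- generate_trial_trace(make_trial(trace_seed = s), cc)
    clean <- despike_and_smooth(trace)
    m <- extract_pupil_measures(clean)
    expect_gte(m$peak_dilation_velocity, m$dilation_velocity)
  }
})

test_that("measures other than baseline are baseline-correction invariant", {
  cc <- noiseless_config()
  trace <- generate_trial_trace(make_trial(), cc)
  m1 <- extract_pupil_measures(trace)
  m2 <- extract_pupil_measures(baseline_correct(trace, m1$baseline_size))
  keep <- setdiff(names(m1), "baseline_size")
  expect_equal(m1[keep], m2[keep], tolerance = 1e-9)
  expect_equal(m2$baseline_size, 0, tolerance = 1e-12)
})

test_that("participant aggregation builds the 14-variable row from medians", {
  one <- extract_pupil_measures(
    generate_trial_trace(make_trial(), noiseless_config()))
  trials <- dplyr::bind_rows(
    dplyr::mutate(one, condition = "PRO"),
    dplyr::mutate(one, condition = "PRO"),
    dplyr::mutate(one, condition = "ANTI"))
  agg <- aggregate_participant(trials)
  expect_equal(ncol(agg$row), 14)
  expect_setequal(
    names(agg$row),
    c(paste0(rep(c("constriction_size", "peak_constriction_velocity",
                   "peak_constriction_time", "dilation_size",
                   "dilation_velocity", "peak_dilation_velocity"), each = 2),
             c("_pro", "_anti")),
      "baseline_size", "onset_latency"))
  # identical trials: medians equal the common value
  expect_equal(agg$row$constriction_size_pro, one$constriction_size)
  # median is robust to a single outlier trial
  trials2 <- trials
  trials2$dilation_velocity <- c(1, 2, 100)
  trials2$condition <- "PRO"
  agg2 <- aggregate_participant(trials2)
  expect_equal(agg2$medians$value[agg2$medians$measure == "dilation_velocity"],
               2)
})
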