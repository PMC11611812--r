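test_that("cohort generation is a pure function of config and seed", {
  cc <- cohort_config(n_participants = 2, seed = 7, trials_per_block = 10,
                      n_blocks = 1)
  a <- generate_cohort(cc)
  b <- generate_cohort(cc)
  expect_identical(a, b)
  cc2 <- cohort_config(n_participants = 2, seed = 8, trials_per_block = 10,
                       n_blocks = 1)
  expect_false(identical(generate_cohort(cc2), a))
})

test_that("default cohort has 240 balanced, interleaved trials per participant", {
  cc <- cohort_config(n_participants = 2, seed = 3)
  coh <- generate_cohort(cc)
  per <- dplyr::count(coh$trials, id, condition)
  expect_true(all(per$n == 120))
  expect_equal(nrow(coh$trials), 2 * 240)
  sides <- dplyr::count(coh$trials, id, side)
  expect_true(all(abs(diff(sides$n)) <= 1))
  # interleaved, not blocked: both conditions appear in each half of a block
  first_half <- coh$trials[coh$trials$id == "P0001", ][1:60, ]
  expect_setequal(unique(first_half$condition), c("PRO", "ANTI"))
})

test_that("config invariants are enforced with informative messages", {
  expect_error(cohort_config(n_participants = 0), "n_participants")
  expect_error(cohort_config(trials_per_block = 15), "trials_per_block")
  expect_error(cohort_config(age_range = c(10, 5)), "age_range")
})

test_that("a zero ANTI-effect schedule generates equal dilation parameters", {
  sched <- age_schedule(anti_effect_gap = function(age) rep(0, length(age)))
  ages <- seq(5, 93, by = 4)
  expect_equal(sched$dilation_rate(ages, "ANTI"),
               sched$dilation_rate(ages, "PRO"))
  cc <- cohort_config(n_participants = 2, seed = 5, trials_per_block = 20,
                      n_blocks = 1, noise_sd = 0)
  coh <- generate_cohort(cc, sched)
  by_cond <- coh$trials |>
    dplyr::group_by(id, condition) |>
    dplyr::summarise(m = mean(dilation_rate_mm_per_s), .groups = "drop") |>
    tidyr::pivot_wider(names_from = condition, values_from = m)
  # parameter draws differ only through trial noise, which is symmetric;
  # the schedule means are identical
  expect_equal(sched$anti_effect_gap(30), 0)
  expect_true(all(abs(by_cond$ANTI - by_cond$PRO) < 0.05))
})

test_that("schedule invariants reject pathological forms", {
  expect_error(age_schedule(baseline_mm = function(age) 4 + age / 50),
               "nonincreasing")
  expect_error(
    age_schedule(anti_effect_gap = function(age) age / 100),
    "nonincreasing")
})

test_that("noiseless traces are exactly representable by their parameters", {
  cc <- noiseless_config()
  p <- make_trial()
  trace <- generate_trial_trace(p, cc)
  # value at the constriction peak is baseline - amplitude exactly
  expect_equal(trace$pupil[trace$t_ms == 900], 5 - 0.4)
  # before the response latency the trace sits at baseline
  expect_true(all(trace$pupil[trace$t_ms < 250] == 5))
  # mean finite-difference slope between peak and stimulus onset equals the
  # dilation rate (independent oracle: slope of the emitted samples)
  seg <- trace$pupil[trace$t_ms >= 900 & trace$t_ms <= 1200]
  slopes <- diff(seg) / 0.002
  expect_equal(mean(slopes), 0.8, tolerance = 1e-9)
  expect_equal(attr(trace, "events")$stim_on - attr(trace, "events")$fp_on,
               1200)
})

test_that("blinks are bounded to the trace and invalidate samples", {
  cc <- noiseless_config()
  p <- make_trial(blink_on_ms = 1400, blink_dur_ms = 150)
  trace <- generate_trial_trace(p, cc)
  expect_true(all(!trace$valid[trace$t_ms >= 1400 & trace$t_ms <= 1550]))
  expect_error(
    generate_trial_trace(make_trial(blink_on_ms = 3150, blink_dur_ms = 200),
                         cc),
    "trace span")
})

test_that("calibration recordings follow the device map", {
  rec <- generate_calibration_recordings(2:12)
  expect_equal(nrow(rec), 11)
  # default map is linear in area, so sqrt(recorded) is linear in diameter
  fit <- lm(sqrt(recorded_area) ~ true_mm, data = rec)
  expect_lt(max(abs(residuals(fit))), 1e-9)
  expect_error(generate_calibration_recordings(c(1, 5)), "2-12")
  expect_error(
    generate_calibration_recordings(2:12, device_map = function(a) -a),
    "increasing")
  # identity map keeps the raw area pattern
  rec_id <- generate_calibration_recordings(c(2, 4, 8),
                                            device_map = function(a) a)
  expect_equal(rec_id$recorded_area, pi * (c(2, 4, 8) / 2)^2)
})

test_that("saccade-measure tables carry the planted factor structure", {
  a <- generate_saccade_measure_table(50, seed = 9)
  b <- generate_saccade_measure_table(50, seed = 9)
  expect_identical(a, b)
  expect_equal(ncol(a), 13)  # id + 12 measures
  pct <- dplyr::select(a, dplyr::ends_with("_pct"))
  expect_true(all(pct >= 0 & pct <= 100))
  srt <- dplyr::select(a, dplyr::ends_with("_srt_ms"))
  expect_true(all(srt >= 90 & srt <= 800))
  expect_equal(dim(attr(a, "latent_scores")), c(50, 4))
  # zero loadings: measures are mutually independent noise
  z <- generate_saccade_measure_table(1500, loadings = matrix(0, 12, 4),
                                      seed = 2)
  R <- correlation_matrix(z)
  expect_lt(max(abs(R[upper.tri(R)])), 0.1)
  # rank-deficient non-zero loadings are rejected
  L <- saccade_factor_loadings()
  L[, 2] <- L[, 1]
  expect_error(generate_saccade_measure_table(10, loadings = L), "rank")
})
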