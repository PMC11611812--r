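test_that("despike-and-smooth leaves a constant trace unchanged", {
  tr <- make_trace(rep(5, 400))
  out <- despike_and_smooth(tr)
  expect_equal(out$pupil, rep(5, 400))
  expect_true(all(out$valid))
})

test_that("a 0.15 mm/ms jump is invalidated and re-interpolated", {
  p <- rep(5, 400)
  p[200] <- 5.30   # 0.3 mm in 2 ms against both neighbours
  out <- despike_and_smooth(make_trace(p))
  expect_lt(max(abs(out$pupil - 5)), 1e-12)
  # a change just below threshold (0.1 mm/ms = 0.2 mm per sample) survives
  q <- rep(5, 400)
  q[200:400] <- 5.19
  out2 <- despike_and_smooth(make_trace(q), smooth_halfwidth = 0)
  expect_equal(out2$pupil[200], 5.19)
})

test_that("boxcar smoothing spreads an impulse over 51 samples", {
  h <- 0.1  # small enough to pass the despike gate
  p <- rep(0.0, 301)
  # shift to a positive pupil level so the despike/validity path is realistic
  p <- p + 5
  p[150] <- 5 + h
  out <- despike_and_smooth(make_trace(p))
  expect_equal(sum(out$pupil - 5), h, tolerance = 1e-12)
  expect_equal(out$pupil[150] - 5, h / 51, tolerance = 1e-12)
  expect_equal(sum(abs(out$pupil - 5) > h / 51 / 100), 51)
})

test_that("long invalid gaps are not interpolated", {
  p <- rep(5, 1000)
  valid <- rep(TRUE, 1000)
  valid[300:500] <- FALSE  # 402 ms gap > 200 ms limit
  out <- despike_and_smooth(make_trace(p, valid = valid))
  expect_true(all(is.na(out$pupil[300:500])))
  valid2 <- rep(TRUE, 1000)
  valid2[300:340] <- FALSE  # 82 ms gap: interpolated
  out2 <- despike_and_smooth(make_trace(p, valid = valid2))
  expect_true(all(out2$valid))
})

test_that("blink detection pads and merges invalid runs", {
  tr <- make_trace(rep(5, 2000))
  expect_equal(nrow(detect_blinks(tr)), 0)
  v <- rep(TRUE, 2000)
  v[tr$t_ms >= 1000 & tr$t_ms <= 1100] <- FALSE
  b <- detect_blinks(make_trace(rep(5, 2000), valid = v))
  expect_equal(b$onset_ms, 950)
  expect_equal(b$offset_ms, 1150)
  v2 <- rep(TRUE, 2000)
  v2[tr$t_ms >= 100 & tr$t_ms <= 200] <- FALSE
  v2[tr$t_ms >= 230 & tr$t_ms <= 300] <- FALSE
  b2 <- detect_blinks(make_trace(rep(5, 2000), valid = v2))
  expect_equal(nrow(b2), 1)
  expect_equal(c(b2$onset_ms, b2$offset_ms), c(50, 350))
})

test_that("saccade detection: threshold, amplitude and ordering", {
  set.seed(42)
  still <- make_trace(rep(5, 1000), gaze_x = rnorm(1000, 0, 0.05),
                      gaze_y = rnorm(1000, 0, 0.05))
  expect_equal(nrow(detect_saccades(still)), 0)

  cc <- noiseless_config()
  trace <- generate_trial_trace(make_trial(srt_ms = 250), cc)
  s <- detect_saccades(trace)
  expect_equal(nrow(s), 1)
  expect_equal(s$amplitude_deg, 10, tolerance = 0.5)
  expect_equal(s$direction, "right")

  # two 5-degree steps 500 ms apart arrive in time order
  t <- seq(0, 2998, by = 2)
  step <- function(t0, amp) {
    dur <- 40
    ifelse(t < t0, 0,
           ifelse(t > t0 + dur, amp,
                  amp * 0.5 * (1 - cos(pi * (t - t0) / dur))))
  }
  gx <- step(500, 5) + step(1000, 5)
  two <- detect_saccades(make_trace(rep(5, length(t)), gaze_x = gx))
  expect_equal(nrow(two), 2)
  expect_true(two$onset_ms[1] < two$onset_ms[2])
  expect_equal(two$amplitude_deg, c(5, 5), tolerance = 0.5)
})

test_that("SRT takes the first large-enough saccade in the response window", {
  trial <- make_trial()
  sacc <- tibble::tibble(onset_ms = 1430, offset_ms = 1490,
                         amplitude_deg = 10, direction = "right",
                         peak_velocity_dps = 300)
  expect_equal(compute_srt(trial, sacc), 230)
  micro <- dplyr::mutate(sacc, amplitude_deg = 1)
  expect_true(is.na(compute_srt(trial, micro)))
  early <- dplyr::mutate(sacc, onset_ms = 1150)
  expect_equal(compute_srt(trial, early), -50)
  outside <- dplyr::mutate(sacc, onset_ms = 1200 + 900)
  expect_true(is.na(compute_srt(trial, outside)))
})

test_that("latency classes partition the SRT axis", {
  expect_equal(classify_latency(120), "express")
  expect_equal(classify_latency(0), "anticipatory")
  expect_equal(classify_latency(90), "express")
  expect_equal(classify_latency(140), "regular")
  expect_equal(classify_latency(89.99), "anticipatory")
  expect_equal(classify_latency(NA_real_), "none")
  grid <- seq(-110, 800, by = 0.5)
  cls <- classify_latency(grid)
  expect_true(all(cls %in% c("anticipatory", "express", "regular")))
  # exactly one class per defined SRT: boundaries are half-open
  expect_equal(sum(cls == "anticipatory"), sum(grid < 90))
  expect_equal(sum(cls == "express"), sum(grid >= 90 & grid < 140))
})

test_that("direction errors are recognised against the instruction", {
  sacc_left <- tibble::tibble(onset_ms = 1400, offset_ms = 1460,
                              amplitude_deg = 10, direction = "left",
                              peak_velocity_dps = 300)
  anti_left <- classify_trial(make_trial(condition = "ANTI", side = "left"),
                              sacc_left)
  expect_true(anti_left$is_direction_error)
  pro_left <- classify_trial(make_trial(condition = "PRO", side = "left"),
                             sacc_left)
  expect_false(pro_left$is_direction_error)
})

test_that("viability screen enumerates every violated rule", {
  no_events <- tibble::tibble(onset_ms = numeric(), offset_ms = numeric(),
                              amplitude_deg = numeric(),
                              direction = character(),
                              peak_velocity_dps = numeric())
  no_blinks <- tibble::tibble(onset_ms = numeric(), offset_ms = numeric())
  clean <- make_trial(); clean$srt_ms <- 230
  clean$latency_class <- "regular"; clean$is_direction_error <- FALSE
  ok <- flag_pupil_viability(clean, no_blinks, no_events)
  expect_true(ok$pupil_viable)
  expect_equal(ok$exclusion_reasons, "")

  blink <- tibble::tibble(onset_ms = 450, offset_ms = 620)
  v1 <- flag_pupil_viability(clean, blink, no_events)
  expect_false(v1$pupil_viable)
  expect_match(v1$exclusion_reasons, "blink_in_fixation")

  fast <- clean; fast$srt_ms <- 85; fast$latency_class <- "anticipatory"
  v2 <- flag_pupil_viability(fast, no_blinks, no_events)
  expect_match(v2$exclusion_reasons, "anticipatory")

  err <- clean; err$is_direction_error <- TRUE
  v3 <- flag_pupil_viability(err, no_blinks, no_events)
  expect_match(v3$exclusion_reasons, "direction_error")

  # monotone: adding a blink to an excluded trial never restores viability
  v4 <- flag_pupil_viability(err, blink, no_events)
  expect_false(v4$pupil_viable)
  expect_match(v4$exclusion_reasons, "blink_in_fixation")
  expect_match(v4$exclusion_reasons, "direction_error")
})

test_that("participant retention follows MoCA and minimum-trial rules", {
  participants <- tibble::tibble(
    id = c("A", "B", "C"),
    age = c(50, 40, 10),
    sex = c("F", "M", "F"),
    moca = c(19, 28, NA))
  trials <- dplyr::bind_rows(
    tibble::tibble(id = "A", condition = rep(c("PRO", "ANTI"), each = 20),
                   pupil_viable = TRUE),
    tibble::tibble(id = "B", condition = c(rep("PRO", 40), rep("ANTI", 9)),
                   pupil_viable = TRUE),
    tibble::tibble(id = "C", condition = rep(c("PRO", "ANTI"), each = 15),
                   pupil_viable = TRUE))
  out <- filter_participants(participants, trials)
  expect_equal(out$retained, c(FALSE, FALSE, TRUE))
  expect_equal(out$n_viable_anti[out$id == "B"], 9)
})
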