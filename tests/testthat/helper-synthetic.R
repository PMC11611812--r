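# deterministic, noise-free building blocks shared across test files

noiseless_config <- function(...) {
  args <- utils::modifyList(
    list(n_participants = 1, seed = 1, noise_sd = 0, blink_rate = 0,
         anticipatory_rate = 0, gaze_noise_sd = 0, baseline_between_sd = 0),
    list(...))
  do.call(cohort_config, args)
}

make_trial <- function(...) {
  defaults <- list(
    id = "P0001", trial_id = 1L, condition = "PRO", side = "right",
    fp_on_ms = 0, gap_on_ms = 1000, stim_on_ms = 1200,
    baseline_mm = 5, constriction_latency_ms = 250,
    constriction_amplitude_mm = 0.4, constriction_peak_ms = 900,
    dilation_rate_mm_per_s = 0.8, srt_ms = 200,
    is_direction_error = FALSE, blink_on_ms = NA_real_,
    blink_dur_ms = NA_real_, trace_seed = NA_integer_)
  tibble::as_tibble(utils::modifyList(defaults, list(...)))
}

# bare trace builder: constant-step time base, all-valid by default
make_trace <- function(pupil, rate = 500, gaze_x = NULL, gaze_y = NULL,
                       valid = NULL, events = list(fp_on = 0, gap_on = 1000,
                                                   stim_on = 1200)) {
  n <- length(pupil)
  tr <- tibble::tibble(
    t_ms = seq(0, by = 1000 / rate, length.out = n),
    gaze_x = gaze_x %||% rep(0, n),
    gaze_y = gaze_y %||% rep(0, n),
    pupil = pupil,
    valid = valid %||% rep(TRUE, n))
  attr(tr, "rate") <- rate
  attr(tr, "pupil_units") <- "mm"
  attr(tr, "events") <- events
  class(tr) <- c("sample_trace", class(tr))
  tr
}

`%||%` <- rlang::`%||%`

# a schedule whose direction-error rate is a small constant (keeps most
# trials viable in compact cohorts)
low_error_schedule <- function(...) {
  age_schedule(error_rate = function(age, condition) {
    rep(0.03, length(age))
  }, ...)
}
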