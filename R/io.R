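#' Read and write sample streams
#'
#' The canonical samples format is a TSV with header
#' `time_ms, gaze_x_deg, gaze_y_deg, pupil_raw, valid`. Timestamps must
#' advance with a constant step (to within one-sample tolerance).
#'
#' @param path File path.
#' @return A sample-trace tibble.
#' @export
read_samples <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time_ms", "gaze_x_deg", "gaze_y_deg", "pupil_raw", "valid")
  missing_cols <- setdiff(need, names(x))
  check_that(length(missing_cols) == 0,
             paste0("samples file is missing column(s): ",
                    paste(missing_cols, collapse = ", ")))
  steps <- diff(x$time_ms)
  step <- as.numeric(names(which.max(table(steps))))
  bad <- which(abs(steps - step) > step + 1e-9)
  if (length(bad)) {
    abort(sprintf("irregular timestamps: first offending row %d (step %g ms, expected %g ms)",
                  bad[1] + 1, steps[bad[1]], step), call = NULL)
  }
  new_trace(t_ms = x$time_ms, gaze_x = x$gaze_x_deg, gaze_y = x$gaze_y_deg,
            pupil = x$pupil_raw, valid = as.logical(x$valid),
            rate = 1000 / step, pupil_units = "area")
}

#' @rdname read_samples
#' @param trace Sample-trace tibble.
#' @export
write_samples <- function(trace, path) {
  readr::write_tsv(tibble(
    time_ms = trace$t_ms, gaze_x_deg = trace$gaze_x,
    gaze_y_deg = trace$gaze_y, pupil_raw = trace$pupil,
    valid = as.integer(trace$valid)
  ), path, progress = FALSE)
  invisible(path)
}

#' Read a trial-events table
#'
#' TSV with header `trial_id, condition, side, fp_on_ms, gap_on_ms,
#' stim_on_ms`. Conditions must be PRO/ANTI and trial ids unique; the IPAST
#' timeline (1,000 ms fixation, 200 ms gap) is validated with a warning for
#' non-standard timing.
#'
#' @param path File path.
#' @return Tibble of trial events.
#' @export
read_events <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("trial_id", "condition", "side", "fp_on_ms", "gap_on_ms",
            "stim_on_ms")
  missing_cols <- setdiff(need, names(x))
  check_that(length(missing_cols) == 0,
             paste0("events file is missing column(s): ",
                    paste(missing_cols, collapse = ", ")))
  check_that(all(x$condition %in% c("PRO", "ANTI")),
             "condition must be PRO or ANTI")
  check_that(!anyDuplicated(x$trial_id), "duplicate trial_id in events file")
  if (any(x$gap_on_ms - x$fp_on_ms != 1000) ||
      any(x$stim_on_ms - x$gap_on_ms != 200)) {
    warn("event timing deviates from the IPAST paradigm (1,000 ms fixation, 200 ms gap)")
  }
  x
}

#' Read a participants table
#'
#' TSV with header `id, age, sex, moca`; an empty `moca` field means the
#' assessment was not administered (children).
#'
#' @param path File path.
#' @return Tibble of participants.
#' @export
read_participants <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         id = readr::col_character(),
                         age = readr::col_double(),
                         sex = readr::col_character(),
                         moca = readr::col_double()))
  need <- c("id", "age", "sex", "moca")
  missing_cols <- setdiff(need, names(x))
  check_that(length(missing_cols) == 0,
             paste0("participants file is missing column(s): ",
                    paste(missing_cols, collapse = ", ")))
  check_that(!anyDuplicated(x$id), "duplicate participant id")
  check_that(all(x$sex %in% c("F", "M")), "sex must be F or M")
  x
}

#' Read a calibration table
#'
#' TSV with header `true_mm, recorded_area`.
#'
#' @param path File path.
#' @return Tibble of calibration recordings.
#' @export
read_calibration <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_that(all(c("true_mm", "recorded_area") %in% names(x)),
             "calibration file needs columns true_mm, recorded_area")
  x
}

run_config_defaults <- function() {
  list(
    seed = 1L,
    n_participants = 50L,
    # acquisition / paradigm
    sampling_rate = 500,
    trials_per_block = 120L,
    n_blocks = 2L,
    fixation_ms = 1000,
    gap_ms = 200,
    stimulus_eccentricity_deg = 10,
    # cleaning
    spike_threshold_mm_per_ms = 0.1,
    smooth_halfwidth_samples = 25L,
    interp_max_ms = 200,
    blink_pad_ms = 50,
    # detection and classification
    saccade_velocity_threshold_dps = 30,
    saccade_min_duration_ms = 6,
    srt_min_amplitude_deg = 2,
    srt_window_ms = c(-110, 800),
    # windows (ms relative to the named event)
    baseline_window_ms = c(150, 200),
    dilation_window_ms = c(-50, 0),
    onset_sliding_window_ms = 20,
    onset_sustain_ms = 40,
    # inclusion
    min_viable_trials = 10L,
    moca_cutoff = 20,
    # statistics
    alpha = 0.05,
    loading_threshold = 0.3,
    oblimin_gamma = 0,
    gam_basis_dim = 10L,
    gam_grid_n = 200L,
    derivative_eps_years = 0.1,
    derivative_draws = 10000L,
    # generator
    noise_sd = 0.02,
    blink_rate = 0.2,
    anticipatory_rate = 0.05,
    emit_device_units = TRUE
  )
}

#' Build a pipeline run configuration
#'
#' All tunable constants of the pipeline with their standard defaults
#' (0.1 mm/ms despike threshold, +/-25-sample smoothing, the measurement
#' windows, SRT classification windows, alpha = 0.05, ...). Unknown keys
#' are rejected.
#'
#' @param ... Overrides of the defaults (see `ipastpupil:::run_config_defaults`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- run_config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  check_that(length(unknown) == 0,
             paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, over)
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file whose keys mirror [run_config()].
#' @return A `run_config` list.
#' @export
load_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Participant-flow accounting report
#'
#' Summarises enrolment and exclusion: enrolled participants split by sex,
#' retained and excluded counts, and the excluded percentage at one decimal.
#' The identity `enrolled = retained + excluded` always holds.
#'
#' @param participants Tibble with at least `sex` and `retained`.
#' @return A list of class `pipeline_report` with the flow counts.
#' @export
pipeline_report <- function(participants) {
  check_that(all(c("sex", "retained") %in% names(participants)),
             "`participants` needs columns sex and retained")
  enrolled <- nrow(participants)
  n_f <- sum(participants$sex == "F")
  n_m <- sum(participants$sex == "M")
  retained <- sum(participants$retained)
  excluded <- enrolled - retained
  structure(list(
    enrolled = enrolled,
    enrolled_female = n_f,
    enrolled_male = n_m,
    retained = retained,
    excluded = excluded,
    excluded_female = sum(participants$sex == "F" & !participants$retained),
    excluded_male = sum(participants$sex == "M" & !participants$retained),
    excluded_pct = round(100 * excluded / enrolled, 1)
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Enrolled: %d (%d F + %d M)\n", x$enrolled,
              x$enrolled_female, x$enrolled_male))
  cat(sprintf("Retained: %d; excluded: %d (%.1f%%)\n", x$retained,
              x$excluded, x$excluded_pct))
  invisible(x)
}
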