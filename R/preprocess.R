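#' Despike and smooth a calibrated pupil trace
#'
#' Transient tracker noise is removed in three steps: (1) samples where the
#' absolute sample-to-sample pupil change exceeds `spike_threshold`
#' (default 0.1 mm/ms) are invalidated; (2) invalid gaps no longer than
#' `interp_max_ms` that are flanked by valid data are linearly interpolated
#' (longer gaps stay invalid -- data are not invented across long losses);
#' (3) each valid sample is replaced by the mean over +/-`smooth_halfwidth`
#' sampling points, with the window shrinking at the trace edges and across
#' any remaining invalid runs.
#'
#' @param trace Sample-trace tibble with `pupil` in mm.
#' @param spike_threshold Maximum plausible pupil change, mm/ms.
#' @param interp_max_ms Longest invalid gap to interpolate, ms.
#' @param smooth_halfwidth Half width of the boxcar, in samples.
#' @return The trace with cleaned `pupil` (NA on invalid samples) and
#'   updated `valid` flags.
#' @export
despike_and_smooth <- function(trace, spike_threshold = 0.1,
                               interp_max_ms = 200, smooth_halfwidth = 25) {
  pupil <- trace$pupil
  valid <- trace$valid & !is.na(pupil)
  n <- length(pupil)
  if (!any(valid)) {
    trace$pupil <- ifelse(valid, pupil, NA_real_)
    trace$valid <- valid
    return(trace)
  }
  dt <- if (n > 1) diff(trace$t_ms[1:2]) else 1
  # 1. despike: invalidate the later sample of any too-fast pair
  if (n > 1) {
    d <- abs(diff(pupil)) / dt
    spike <- c(FALSE, d > spike_threshold) & valid & c(FALSE, valid[-n])
    valid[spike] <- FALSE
  }
  # 2. interpolate short invalid gaps flanked by valid data
  runs <- true_runs(!valid)
  if (runs$n) {
    for (i in seq_len(runs$n)) {
      a <- runs$start[i]; b <- runs$end[i]
      gap_ms <- (b - a + 1) * dt
      if (gap_ms <= interp_max_ms && a > 1 && b < n) {
        idx <- a:b
        pupil[idx] <- pupil[a - 1] +
          (pupil[b + 1] - pupil[a - 1]) * (idx - (a - 1)) / (b + 1 - (a - 1))
        valid[idx] <- TRUE
      }
    }
  }
  # 3. centered boxcar over valid samples
  x <- ifelse(valid, pupil, NA_real_)
  sm <- boxcar_mean(x, smooth_halfwidth)
  trace$pupil <- ifelse(valid, sm, NA_real_)
  trace$valid <- valid
  trace
}

#' Detect blinks from validity flags
#'
#' A blink is a maximal run of invalid samples, padded by `pad_ms` on both
#' sides (eyelid artifacts flank the tracker's data loss); padded intervals
#' that overlap are merged.
#'
#' @param trace Sample-trace tibble with raw `valid` flags.
#' @param pad_ms Padding applied to each side of an invalid run, ms.
#' @return Tibble with columns `onset_ms`, `offset_ms` (possibly 0 rows).
#' @export
detect_blinks <- function(trace, pad_ms = 50) {
  runs <- true_runs(!trace$valid)
  if (!runs$n) return(tibble(onset_ms = numeric(), offset_ms = numeric()))
  on <- trace$t_ms[runs$start] - pad_ms
  off <- trace$t_ms[runs$end] + pad_ms
  merge_intervals(on, off)
}

merge_intervals <- function(on, off) {
  o <- order(on)
  on <- on[o]; off <- off[o]
  res_on <- on[1]; res_off <- off[1]
  if (length(on) > 1) {
    for (i in 2:length(on)) {
      if (on[i] <= res_off[length(res_off)]) {
        res_off[length(res_off)] <- max(res_off[length(res_off)], off[i])
      } else {
        res_on <- c(res_on, on[i]); res_off <- c(res_off, off[i])
      }
    }
  }
  tibble(onset_ms = res_on, offset_ms = res_off)
}

#' Detect saccades with a velocity threshold
#'
#' Gaze channels are smoothed with a 5-sample boxcar, 2-D velocity is taken
#' by central differences, and saccades are maximal runs where speed exceeds
#' `velocity_threshold` (default 30 deg/s) for at least `min_duration_ms`.
#' Amplitude is the Euclidean gaze displacement from onset to offset and
#' direction the sign of the horizontal displacement.
#'
#' @param trace Sample-trace tibble with `gaze_x`, `gaze_y` in degrees.
#' @param velocity_threshold Speed threshold, deg/s.
#' @param min_duration_ms Minimum above-threshold duration, ms.
#' @return Tibble: `onset_ms`, `offset_ms`, `amplitude_deg`, `direction`
#'   (`"left"`/`"right"`), `peak_velocity_dps`.
#' @export
detect_saccades <- function(trace, velocity_threshold = 30,
                            min_duration_ms = 6) {
  n <- nrow(trace)
  empty <- tibble(onset_ms = numeric(), offset_ms = numeric(),
                  amplitude_deg = numeric(), direction = character(),
                  peak_velocity_dps = numeric())
  if (n < 7) return(empty)
  dt_s <- diff(trace$t_ms[1:2]) / 1000
  gx <- boxcar_mean(trace$gaze_x, 2L)  # 5-sample smoothing
  gy <- boxcar_mean(trace$gaze_y, 2L)
  vx <- central_diff(gx, dt_s)
  vy <- central_diff(gy, dt_s)
  speed <- sqrt(vx^2 + vy^2)
  min_samples <- max(1L, ceiling(min_duration_ms / (dt_s * 1000)))
  runs <- true_runs(speed > velocity_threshold)
  keep <- runs$end - runs$start + 1L >= min_samples
  starts <- runs$start[keep]; ends <- runs$end[keep]
  if (!length(starts)) return(empty)
  dx <- gx[ends] - gx[starts]
  dy <- gy[ends] - gy[starts]
  pk <- vapply(seq_along(starts),
               function(i) max(speed[starts[i]:ends[i]]), numeric(1))
  new_tibble(list(onset_ms = trace$t_ms[starts],
                  offset_ms = trace$t_ms[ends],
                  amplitude_deg = sqrt(dx^2 + dy^2),
                  direction = ifelse(dx >= 0, "right", "left"),
                  peak_velocity_dps = pk), nrow = length(starts))
}

central_diff <- function(x, dt_s) {
  n <- length(x)
  v <- rep(NA_real_, n)
  if (n >= 3) v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt_s)
  if (n >= 2) {
    v[1] <- (x[2] - x[1]) / dt_s
    v[n] <- (x[n] - x[n - 1]) / dt_s
  }
  v
}

# first saccade away from fixation within the SRT window
first_response_saccade <- function(stim_on, saccades, min_amplitude = 2,
                                   window_ms = c(-110, 800)) {
  if (!nrow(saccades)) return(NULL)
  keep <- which(saccades$amplitude_deg >= min_amplitude &
                  saccades$onset_ms >= stim_on + window_ms[1] &
                  saccades$onset_ms <= stim_on + window_ms[2])
  if (!length(keep)) return(NULL)
  first <- keep[which.min(saccades$onset_ms[keep])]
  list(onset_ms = saccades$onset_ms[first],
       direction = saccades$direction[first])
}

#' Saccadic reaction time of a trial
#'
#' Time from stimulus appearance to the onset of the first saccade away from
#' fixation: the first detected saccade of at least `min_amplitude` (2
#' degrees, the same amplitude convention as the fixation-period exclusion)
#' whose onset falls within -110 to +800 ms of stimulus onset. `NA` if none.
#'
#' @param trial One-row tibble (or list) with `stim_on_ms`.
#' @param saccades [detect_saccades()] output for the trial's trace.
#' @param min_amplitude Minimum saccade amplitude, degrees.
#' @return SRT in ms, or `NA`.
#' @export
compute_srt <- function(trial, saccades, min_amplitude = 2) {
  s <- first_response_saccade(trial$stim_on_ms, saccades, min_amplitude)
  if (is.null(s)) NA_real_ else s$onset_ms - trial$stim_on_ms
}

#' Classify a trial by saccade latency and direction
#'
#' Latency classes partition the SRT axis: anticipatory `[-110, 90)` ms
#' (a guess launched before the stimulus could be processed), express
#' `[90, 140)` ms, regular `[140, 800]` ms; anything else (or no saccade) is
#' `"none"`. The trial is a direction error when the first response
#' saccade's direction contradicts the instruction -- toward the stimulus
#' for PRO, away from it for ANTI.
#'
#' @param trial One-row tibble with `condition`, `side`, `stim_on_ms`.
#' @param saccades [detect_saccades()] output for the trial's trace.
#' @param min_amplitude Minimum saccade amplitude, degrees.
#' @return The trial row with `srt_ms`, `latency_class` and
#'   `is_direction_error` filled in.
#' @export
classify_trial <- function(trial, saccades, min_amplitude = 2) {
  s <- first_response_saccade(trial$stim_on_ms, saccades, min_amplitude)
  srt <- if (is.null(s)) NA_real_ else s$onset_ms - trial$stim_on_ms
  trial$srt_ms <- srt
  trial$latency_class <- classify_latency(srt)
  if (is.null(s)) {
    trial$is_direction_error <- NA
  } else {
    instructed <- if (trial$condition == "PRO") trial$side else
      setdiff(c("left", "right"), trial$side)
    trial$is_direction_error <- s$direction != instructed
  }
  trial
}

#' @rdname classify_trial
#' @param srt_ms Numeric vector of saccadic reaction times, ms.
#' @export
classify_latency <- function(srt_ms) {
  dplyr::case_when(
    is.na(srt_ms) ~ "none",
    srt_ms >= -110 & srt_ms < 90 ~ "anticipatory",
    srt_ms >= 90 & srt_ms < 140 ~ "express",
    srt_ms >= 140 & srt_ms <= 800 ~ "regular",
    TRUE ~ "none"
  )
}

#' Flag whether a trial's pupil data are usable
#'
#' The pupil analysis epoch runs from fixation-point onset to stimulus
#' onset. A trial is viable only if (1) no blink overlaps that epoch, (2) no
#' saccade larger than 2 degrees occurs within it, (3) the response saccade
#' came later than 90 ms after the stimulus, and (4) the response went in
#' the instructed direction. Every violated rule is recorded in
#' `exclusion_reasons` (semicolon-joined).
#'
#' @param trial A classified trial row (see [classify_trial()]).
#' @param blinks,saccades Event tables for the trial's trace.
#' @param max_fix_saccade_deg Largest saccade tolerated during fixation.
#' @return The trial row with `pupil_viable` and `exclusion_reasons`.
#' @export
flag_pupil_viability <- function(trial, blinks, saccades,
                                 max_fix_saccade_deg = 2) {
  fp <- trial$fp_on_ms; stim <- trial$stim_on_ms
  reasons <- character()
  if (nrow(blinks) &&
      any(blinks$onset_ms <= stim & blinks$offset_ms >= fp)) {
    reasons <- c(reasons, "blink_in_fixation")
  }
  if (nrow(saccades)) {
    fix_sacc <- saccades$amplitude_deg > max_fix_saccade_deg &
      saccades$onset_ms <= stim & saccades$offset_ms >= fp
    if (any(fix_sacc)) reasons <- c(reasons, "saccade_in_fixation")
  }
  if (is.na(trial$srt_ms)) {
    reasons <- c(reasons, "no_saccade")
  } else if (trial$srt_ms <= 90) {
    reasons <- c(reasons, "anticipatory")
  }
  if (isTRUE(trial$is_direction_error)) {
    reasons <- c(reasons, "direction_error")
  }
  trial$pupil_viable <- length(reasons) == 0
  trial$exclusion_reasons <- paste(reasons, collapse = ";")
  trial
}

#' Apply participant-level inclusion rules
#'
#' A participant is retained when their MoCA score (administered to adults
#' only; `NA` means not administered) is at or above `moca_cutoff`, and they
#' contributed at least `min_trials` viable correct trials in *each* of the
#' PRO and ANTI conditions.
#'
#' @param participants Tibble with `id`, `age`, `sex`, `moca`.
#' @param trials Tibble of flagged trials (`id`, `condition`,
#'   `pupil_viable`).
#' @param min_trials Minimum viable trials per condition (default 10).
#' @param moca_cutoff MoCA inclusion cut-off (default 20).
#' @return `participants` with `n_viable_pro`, `n_viable_anti`, `retained`.
#' @export
filter_participants <- function(participants, trials, min_trials = 10,
                                moca_cutoff = 20) {
  counts <- trials |>
    filter(.data$pupil_viable) |>
    dplyr::count(.data$id, .data$condition) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "n",
                       values_fill = 0L)
  for (col in c("PRO", "ANTI")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  out <- participants |>
    left_join(counts, by = "id") |>
    mutate(
      n_viable_pro = dplyr::coalesce(.data$PRO, 0L),
      n_viable_anti = dplyr::coalesce(.data$ANTI, 0L),
      moca_pass = is.na(.data$moca) | .data$moca >= moca_cutoff,
      retained = .data$moca_pass &
        .data$n_viable_pro >= min_trials & .data$n_viable_anti >= min_trials
    ) |>
    select(-dplyr::any_of(c("PRO", "ANTI")))
  out
}
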