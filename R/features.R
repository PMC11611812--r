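#' Baseline pupil size
#'
#' Mean pupil diameter over the closed epoch 150-200 ms after fixation-point
#' onset, before the light-evoked response begins. At 500 Hz the closed
#' window holds 26 samples. If any sample in the window is invalid the
#' measure is undefined for the trial.
#'
#' @param trace Cleaned sample-trace tibble (pupil in mm).
#' @param fp_on Fixation-point onset, ms.
#' @param window Window relative to `fp_on`, ms (default `c(150, 200)`).
#' @return Baseline in mm, or `NA`.
#' @export
baseline_size <- function(trace, fp_on, window = c(150, 200)) {
  idx <- trace$t_ms >= fp_on + window[1] & trace$t_ms <= fp_on + window[2]
  if (!any(idx) || any(!trace$valid[idx]) || anyNA(trace$pupil[idx])) {
    return(NA_real_)
  }
  mean(trace$pupil[idx])
}

#' Subtract the trial baseline from a trace
#'
#' @param trace Sample-trace tibble.
#' @param baseline Baseline pupil size, mm.
#' @return The trace with `pupil` baseline-corrected.
#' @export
baseline_correct <- function(trace, baseline) {
  check_that(is.finite(baseline), "`baseline` must be defined")
  trace$pupil <- trace$pupil - baseline
  trace
}

#' Pupil velocity series
#'
#' Central-difference velocity `(x[i+1] - x[i-1]) / (2 dt)` in mm/s,
#' one-sided at the trace ends, `NA` wherever a neighbouring sample is
#' invalid.
#'
#' @param trace Sample-trace tibble (pupil in mm).
#' @return Numeric vector of velocities, mm/s, aligned with `trace$t_ms`.
#' @export
pupil_velocity <- function(trace) {
  x <- ifelse(trace$valid, trace$pupil, NA_real_)
  dt_s <- if (nrow(trace) > 1) diff(trace$t_ms[1:2]) / 1000 else 1
  central_diff(x, dt_s)
}

#' Pupil response onset latency
#'
#' The earliest time at which pupil velocity departs from its baseline
#' distribution: a 20 ms window slides from 200 ms after fixation-point
#' onset; at each start the window's velocities are compared against the
#' mean velocity of the baseline epoch (one-sample t-test, two-sided
#' `alpha`), and the onset is the first start whose test is significant and
#' stays significant for the following `sustain_ms`. On noise-free data a
#' window with zero spread counts as significant only if its mean actually
#' differs from the baseline mean.
#'
#' @param trace Cleaned sample-trace tibble.
#' @param fp_on,stim_on Fixation-point and stimulus onsets, ms.
#' @param window_ms Sliding-window length, ms (default 20).
#' @param sustain_ms How long past the candidate the criterion must hold.
#' @param alpha Two-sided significance level.
#' @param baseline_window Baseline velocity epoch relative to `fp_on`, ms.
#' @return Latency in ms after `fp_on`, or `NA` if no window qualifies
#'   before stimulus onset.
#' @export
onset_latency <- function(trace, fp_on, stim_on, window_ms = 20,
                          sustain_ms = 40, alpha = 0.05,
                          baseline_window = c(150, 200)) {
  v <- pupil_velocity(trace)
  t <- trace$t_ms
  dt <- if (length(t) > 1) diff(t[1:2]) else 1
  base_idx <- t >= fp_on + baseline_window[1] & t <= fp_on + baseline_window[2]
  vb <- v[base_idx]
  if (!length(vb) || anyNA(vb)) return(NA_real_)
  mu0 <- mean(vb)
  w <- max(2L, round(window_ms / dt))
  starts <- which(t >= fp_on + 200 & t <= stim_on - window_ms)
  if (!length(starts)) return(NA_real_)
  n <- length(v)
  m <- roll_sum(ifelse(is.na(v), 0, v), w) / w
  has_na <- roll_sum(as.numeric(is.na(v)), w) > 0
  s2 <- roll_sum(ifelse(is.na(v), 0, v)^2, w)
  sdw <- sqrt(pmax(s2 / w - m^2, 0) * w / (w - 1))
  tstat <- ifelse(sdw > 1e-12, (m - mu0) / (sdw / sqrt(w)), NA_real_)
  p <- 2 * pt(-abs(tstat), df = w - 1)
  sig <- ifelse(is.na(tstat), abs(m - mu0) > 1e-9, p < alpha)
  sig[has_na] <- FALSE
  k_sustain <- round(sustain_ms / dt)
  starts <- starts[starts <= length(sig)]
  for (s0 in starts) {
    upto <- min(s0 + k_sustain, length(sig))
    if (all(sig[s0:upto])) return(t[s0] - fp_on)
  }
  NA_real_
}

#' Constriction features of a trial
#'
#' Peak constriction is the pupil minimum over the fixation epoch, searched
#' from 200 ms after fixation-point onset (the pupil cannot respond before
#' its onset latency) up to and including stimulus onset. Constriction size
#' is baseline minus that minimum; peak constriction velocity is the most
#' negative velocity between fixation-point onset and the peak.
#'
#' @param trace Cleaned sample-trace tibble.
#' @param fp_on,stim_on Event times, ms.
#' @param baseline Baseline pupil size, mm.
#' @return A list: `constriction_size` (mm), `peak_constriction_time`
#'   (ms after `fp_on`), `peak_constriction_velocity` (mm/s), `degenerate`
#'   (flag: minimum sat at the search-window start, i.e. the trace only
#'   dilated).
#' @export
constriction_features <- function(trace, fp_on, stim_on, baseline) {
  t <- trace$t_ms
  idx <- which(t > fp_on + 200 & t <= stim_on & trace$valid &
                 !is.na(trace$pupil))
  if (!length(idx) || !is.finite(baseline)) {
    return(list(constriction_size = NA_real_,
                peak_constriction_time = NA_real_,
                peak_constriction_velocity = NA_real_, degenerate = TRUE))
  }
  imin <- idx[which.min(trace$pupil[idx])]
  peak_t <- t[imin]
  v <- pupil_velocity(trace)
  vel_idx <- which(t > fp_on & t <= peak_t)
  pcv <- suppressWarnings(min(v[vel_idx], na.rm = TRUE))
  if (!is.finite(pcv)) pcv <- NA_real_
  list(
    constriction_size = baseline - trace$pupil[imin],
    peak_constriction_time = peak_t - fp_on,
    peak_constriction_velocity = pcv,
    degenerate = imin == idx[1]
  )
}

#' Dilation features of a trial
#'
#' Dilation size is the mean pupil over the closed 50 ms window before
#' stimulus onset minus the pupil at peak constriction; dilation velocity is
#' the mean velocity over the same window; peak dilation velocity is the
#' largest velocity between peak constriction and stimulus onset.
#'
#' @param trace Cleaned sample-trace tibble.
#' @param peak_time Peak-constriction time, ms after `fp_on`.
#' @param fp_on,stim_on Event times, ms.
#' @return A list: `dilation_size` (mm), `dilation_velocity` (mm/s),
#'   `peak_dilation_velocity` (mm/s), `degenerate` (peak too close to
#'   stimulus onset for the pre-target window).
#' @export
dilation_features <- function(trace, peak_time, fp_on, stim_on) {
  t <- trace$t_ms
  peak_abs <- fp_on + peak_time
  degenerate <- !is.finite(peak_time) || peak_abs >= stim_on - 50
  win <- t >= stim_on - 50 & t <= stim_on
  if (degenerate || !any(win) || any(!trace$valid[win]) ||
      anyNA(trace$pupil[win])) {
    return(list(dilation_size = NA_real_, dilation_velocity = NA_real_,
                peak_dilation_velocity = NA_real_, degenerate = TRUE))
  }
  v <- pupil_velocity(trace)
  peak_idx <- which.min(abs(t - peak_abs))
  post <- t > peak_abs & t <= stim_on
  pdv <- suppressWarnings(max(v[post], na.rm = TRUE))
  if (!is.finite(pdv)) pdv <- NA_real_
  list(
    dilation_size = mean(trace$pupil[win]) - trace$pupil[peak_idx],
    dilation_velocity = mean(v[win]),
    peak_dilation_velocity = pdv,
    degenerate = FALSE
  )
}

#' Extract the eight pupil measures from one trial
#'
#' Convenience wrapper running [baseline_size()], [onset_latency()],
#' [constriction_features()] and [dilation_features()] on a cleaned trace.
#'
#' @param trace Cleaned sample-trace tibble (pupil in mm).
#' @param fp_on,stim_on Event times, ms; default taken from the trace's
#'   `events` attribute.
#' @return One-row tibble with the eight measures.
#' @export
extract_pupil_measures <- function(trace, fp_on = NULL, stim_on = NULL) {
  ev <- attr(trace, "events")
  fp_on <- fp_on %||% ev$fp_on %||% 0
  stim_on <- stim_on %||% ev$stim_on %||% 1200
  b <- baseline_size(trace, fp_on)
  ol <- onset_latency(trace, fp_on, stim_on)
  cf <- constriction_features(trace, fp_on, stim_on, b)
  df <- dilation_features(trace, cf$peak_constriction_time, fp_on, stim_on)
  new_tibble(list(
    baseline_size = b,
    onset_latency = ol,
    constriction_size = cf$constriction_size,
    peak_constriction_time = cf$peak_constriction_time,
    peak_constriction_velocity = cf$peak_constriction_velocity,
    dilation_size = df$dilation_size,
    dilation_velocity = df$dilation_velocity,
    peak_dilation_velocity = df$peak_dilation_velocity
  ), nrow = 1L)
}

condition_split_measures <- function() {
  c("constriction_size", "peak_constriction_velocity",
    "peak_constriction_time", "dilation_size", "dilation_velocity",
    "peak_dilation_velocity")
}

pooled_measures <- function() c("baseline_size", "onset_latency")

#' Aggregate a participant's trial measures
#'
#' Takes the per-trial measures of one participant's viable trials and
#' returns the per-condition medians of each measure together with the
#' 14-variable analysis row: six measures split by condition
#' (`_pro`/`_anti` suffixes) plus baseline size and onset latency pooled
#' across conditions (these two show no task modulation).
#'
#' @param trial_measures Tibble of per-trial measures with a `condition`
#'   column (viable trials only).
#' @return A list: `medians` (long tibble: condition, measure, value) and
#'   `row` (one-row tibble with the 14 variables; `NA` where a measure was
#'   undefined on every contributing trial).
#' @export
aggregate_participant <- function(trial_measures) {
  split_vars <- condition_split_measures()
  pool_vars <- pooled_measures()
  med_long <- trial_measures |>
    select(dplyr::all_of(c("condition", split_vars, pool_vars))) |>
    tidyr::pivot_longer(-"condition", names_to = "measure") |>
    group_by(.data$condition, .data$measure) |>
    summarise(value = stats::median(.data$value, na.rm = TRUE),
              .groups = "drop")
  row <- list()
  for (m in split_vars) {
    for (cond in c("PRO", "ANTI")) {
      val <- med_long$value[med_long$condition == cond & med_long$measure == m]
      row[[paste0(m, "_", tolower(cond))]] <-
        if (length(val)) val else NA_real_
    }
  }
  for (m in pool_vars) {
    row[[m]] <- stats::median(trial_measures[[m]], na.rm = TRUE)
  }
  row_tbl <- as_tibble(row)
  ord <- c(as.vector(t(outer(split_vars, c("_pro", "_anti"), paste0))),
           pool_vars)
  list(medians = med_long, row = row_tbl[, ord])
}
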