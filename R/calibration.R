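#' Fit a false-pupil calibration curve
#'
#' Video eye trackers report pupil size in arbitrary area units. Recording a
#' series of artificial pupils of known diameter (2-12 mm) gives paired
#' (diameter, recorded area) observations; because area grows with the square
#' of diameter, the conversion is performed as a linear interpolation over
#' the *square root* of the recorded area. Replicate recordings per size are
#' averaged in area space before the square root is taken.
#'
#' @param recordings Data frame with columns `true_mm` and `recorded_area`.
#' @param strict_range If `TRUE`, reject sizes outside the 2-12 mm
#'   false-pupil series (default `FALSE`).
#' @return An object of class `calibration_curve`: a tibble of nodes
#'   (`sqrt_area`, `diameter_mm`), sorted ascending.
#' @export
fit_calibration <- function(recordings, strict_range = FALSE) {
  check_that(is.data.frame(recordings) &&
               all(c("true_mm", "recorded_area") %in% names(recordings)),
             "`recordings` needs columns true_mm and recorded_area")
  check_that(all(recordings$recorded_area > 0),
             "recorded_area must be positive")
  if (strict_range) {
    check_that(all(recordings$true_mm >= 2 & recordings$true_mm <= 12),
               "false-pupil sizes must lie within 2-12 mm")
  }
  nodes <- recordings |>
    group_by(diameter_mm = .data$true_mm) |>
    summarise(sqrt_area = sqrt(mean(.data$recorded_area)), .groups = "drop") |>
    arrange(.data$diameter_mm) |>
    select(sqrt_area, diameter_mm)
  check_that(nrow(nodes) >= 2, "need at least 2 distinct false-pupil sizes")
  bad <- which(diff(nodes$sqrt_area) <= 0)
  if (length(bad)) {
    abort(sprintf(
      "sqrt(recorded area) is not strictly increasing in diameter between %g mm and %g mm",
      nodes$diameter_mm[bad[1]], nodes$diameter_mm[bad[1] + 1]), call = NULL)
  }
  structure(nodes, class = c("calibration_curve", class(nodes)))
}

#' Convert a raw-area trace to pupil diameter in mm
#'
#' Applies the calibration curve sample-wise: `mm` is the piecewise-linear
#' interpolation of `sqrt(raw area)` over the curve's nodes. Values beyond
#' the node range are linearly extrapolated from the terminal segments
#' (a child's pupil can exceed the largest false pupil); a warning is issued
#' when more than 5% of valid samples extrapolate. Invalid samples stay
#' invalid; a negative raw area on a valid sample is marked invalid.
#'
#' @param curve A [fit_calibration()] result.
#' @param trace A sample-trace tibble whose `pupil` column holds raw area.
#' @return The trace with `pupil` in mm (`pupil_units` attribute updated).
#' @export
apply_calibration <- function(curve, trace) {
  check_that(inherits(curve, "calibration_curve"),
             "`curve` must be a calibration_curve")
  raw <- trace$pupil
  valid <- trace$valid
  neg <- valid & !is.na(raw) & raw < 0
  if (any(neg)) {
    warn(sprintf("%d valid sample(s) had negative raw pupil area; marked invalid",
                 sum(neg)))
    valid[neg] <- FALSE
  }
  s <- sqrt(pmax(raw, 0))
  mm <- linear_interp_extrap(curve$sqrt_area, curve$diameter_mm, s)
  out_of_range <- valid & (s < min(curve$sqrt_area) | s > max(curve$sqrt_area))
  if (mean(out_of_range[valid]) > 0.05 && any(valid)) {
    warn(sprintf("%.1f%% of valid samples fall outside the calibration range (extrapolated)",
                 100 * mean(out_of_range[valid])))
  }
  trace$pupil <- mm
  trace$valid <- valid
  attr(trace, "pupil_units") <- "mm"
  trace
}

# piecewise-linear interpolation with linear extrapolation from end segments
linear_interp_extrap <- function(x, y, xout) {
  out <- approx(x, y, xout = xout, rule = 2)$y
  n <- length(x)
  lo <- xout < x[1]
  hi <- xout > x[n]
  if (any(lo)) {
    s <- (y[2] - y[1]) / (x[2] - x[1])
    out[lo] <- y[1] + s * (xout[lo] - x[1])
  }
  if (any(hi)) {
    s <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    out[hi] <- y[n] + s * (xout[hi] - x[n])
  }
  out
}
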