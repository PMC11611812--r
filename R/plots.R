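#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_ribbon geom_point
#'   geom_tile geom_col geom_hline geom_vline labs scale_fill_gradient2
#'   theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a pupil trace with task events
#'
#' @param trace Sample-trace tibble.
#' @return A ggplot.
#' @export
plot_trace <- function(trace) {
  ev <- attr(trace, "events") %||% list(fp_on = 0, gap_on = 1000,
                                        stim_on = 1200)
  ggplot(trace, aes(x = .data$t_ms, y = .data$pupil)) +
    geom_line(na.rm = TRUE) +
    geom_vline(xintercept = c(ev$fp_on, ev$gap_on, ev$stim_on),
               linetype = "dashed", colour = "grey50") +
    labs(x = "Time (ms)", y = "Pupil diameter (mm)") +
    theme_minimal()
}

#' @rdname plot_trace
#' @param object Result object to plot.
#' @param ... Unused.
#' @method autoplot anti_effect_table
#' @export
autoplot.anti_effect_table <- function(object, ...) {
  ggplot(object, aes(x = .data$measure, y = .data$median_effect,
                     fill = .data$significant)) +
    geom_col() +
    geom_hline(yintercept = 0) +
    labs(x = NULL, y = "Median ANTI - PRO effect",
         fill = "p < 0.05") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @rdname plot_trace
#' @param object Result object to plot.
#' @param ... Unused.
#' @method autoplot factor_model
#' @export
autoplot.factor_model <- function(object, ...) {
  tidy.factor_model(object) |>
    ggplot(aes(x = .data$factor, y = .data$measure,
               fill = .data$loading)) +
    geom_tile() +
    scale_fill_gradient2(limits = c(-1, 1) * max(abs(object$pattern), 1)) +
    labs(x = NULL, y = NULL, fill = "Pattern\nloading") +
    theme_minimal()
}

#' @rdname plot_trace
#' @param object Result object to plot.
#' @param ... Unused.
#' @method autoplot factor_cor
#' @export
autoplot.factor_cor <- function(object, ...) {
  tidy.factor_cor(object) |>
    ggplot(aes(x = .data$saccade_factor, y = .data$pupil_factor,
               fill = ifelse(.data$significant, .data$rho, NA))) +
    geom_tile(colour = "grey80") +
    scale_fill_gradient2(na.value = "white", limits = c(-1, 1)) +
    labs(x = "Saccade factor", y = "Pupil factor", fill = "Spearman rho\n(Bonferroni)") +
    theme_minimal()
}

#' @rdname plot_trace
#' @param object Result object to plot.
#' @param ... Unused.
#' @method autoplot gam_fit
#' @export
autoplot.gam_fit <- function(object, ...) {
  g <- object$grid
  p <- ggplot(g, aes(x = .data$age, y = .data$fit)) +
    geom_ribbon(aes(ymin = .data$lo, ymax = .data$hi), alpha = 0.25) +
    geom_line() +
    labs(x = "Age (years)", y = "Fitted value") +
    theme_minimal()
  if (!is.null(object$windows) && nrow(object$windows)) {
    p <- p + ggplot2::geom_rect(
      data = object$windows,
      aes(xmin = .data$age_lo, xmax = .data$age_hi),
      ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "firebrick",
      inherit.aes = FALSE)
  }
  p
}

#' @rdname plot_trace
#' @param object Result object to plot.
#' @param ... Unused.
#' @method autoplot sex_diff
#' @export
autoplot.sex_diff <- function(object, ...) {
  g <- object$grid
  p <- ggplot(g, aes(x = .data$age, y = .data$diff)) +
    geom_ribbon(aes(ymin = .data$lo, ymax = .data$hi), alpha = 0.25) +
    geom_line() +
    geom_hline(yintercept = 0, linetype = "dashed") +
    labs(x = "Age (years)", y = "Female - male difference (mm)") +
    theme_minimal()
  if (nrow(object$windows)) {
    p <- p + ggplot2::geom_rect(
      data = object$windows,
      aes(xmin = .data$age_lo, xmax = .data$age_hi),
      ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "steelblue",
      inherit.aes = FALSE)
  }
  p
}

#' Plot smoothing-spline trajectories per condition
#'
#' @param fits Output of [smoothing_spline_fit()] (optionally with a
#'   `measure` column for faceting).
#' @return A ggplot.
#' @export
plot_spline_fits <- function(fits) {
  p <- ggplot(fits, aes(x = .data$age, y = .data$fit,
                        colour = .data$condition)) +
    geom_line() +
    labs(x = "Age (years)", y = "Measure value", colour = "Condition") +
    theme_minimal()
  if ("measure" %in% names(fits)) {
    p <- p + facet_wrap(~measure, scales = "free_y")
  }
  p
}
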