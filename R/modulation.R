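#' Per-participant ANTI-effects
#'
#' The ANTI-effect of a pupil measure is the participant's ANTI-condition
#' median minus their PRO-condition median (ANTI - PRO). Participants
#' missing either condition median for a measure are omitted for that
#' measure.
#'
#' @param medians Long tibble of per-participant condition medians with
#'   columns `id`, `condition` (`"PRO"`/`"ANTI"`), `measure`, `value`.
#' @return Tibble with columns `id`, `measure`, `effect`.
#' @export
anti_effect <- function(medians) {
  check_that(all(c("id", "condition", "measure", "value") %in% names(medians)),
             "`medians` needs columns id, condition, measure, value")
  medians |>
    tidyr::pivot_wider(id_cols = c("id", "measure"),
                       names_from = "condition", values_from = "value") |>
    filter(!is.na(.data$ANTI), !is.na(.data$PRO)) |>
    mutate(effect = .data$ANTI - .data$PRO) |>
    select("id", "measure", "effect")
}

#' Wilcoxon signed-rank test of an ANTI-effect
#'
#' Two-sided Wilcoxon signed-rank test of the per-participant effects
#' against zero. Zero effects are dropped (standard signed-rank practice);
#' the exact null distribution is used for 25 or fewer non-zero effects and
#' the normal approximation with continuity correction above that.
#'
#' @param effects Numeric vector of per-participant effects (ANTI - PRO).
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble: `n`, `n_zero`, `median_effect`, `statistic` (W),
#'   `p_value`, `significant`, `degenerate` (all effects zero).
#' @export
anti_effect_test <- function(effects, alpha = 0.05) {
  effects <- effects[is.finite(effects)]
  n_zero <- sum(effects == 0)
  nz <- effects[effects != 0]
  if (!length(nz)) {
    return(tibble(n = length(effects), n_zero = n_zero,
                  median_effect = 0, statistic = NA_real_, p_value = 1,
                  significant = FALSE, degenerate = TRUE))
  }
  check_that(length(nz) >= 6,
             "need at least 6 non-zero effects for the signed-rank test")
  wt <- suppressWarnings(
    wilcox.test(nz, mu = 0, alternative = "two.sided",
                exact = length(nz) <= 25, correct = TRUE)
  )
  tibble(n = length(effects), n_zero = n_zero,
         median_effect = stats::median(effects),
         statistic = unname(wt$statistic), p_value = wt$p.value,
         significant = wt$p.value < alpha, degenerate = FALSE)
}

#' Task-modulation table across all measures
#'
#' Runs [anti_effect_test()] for every measure in an [anti_effect()] table.
#'
#' @param effects Tibble with columns `measure`, `effect` (and `id`).
#' @param alpha Significance level.
#' @return Tibble of class `anti_effect_table`, one row per measure.
#' @export
anti_effect_table <- function(effects, alpha = 0.05) {
  out <- effects |>
    group_by(.data$measure) |>
    dplyr::group_modify(~ anti_effect_test(.x$effect, alpha = alpha)) |>
    ungroup()
  class(out) <- c("anti_effect_table", class(out))
  out
}
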