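#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted factor model
#'
#' One row per measure-factor pair with the pattern loading and its
#' significance under the |loading| > 0.3 convention.
#'
#' @param x A [fit_factor_model()] object.
#' @param threshold Loading threshold (default 0.3).
#' @param ... Unused.
#' @return A tibble: `measure`, `factor`, `loading`, `significant`,
#'   `communality`.
#' @method tidy factor_model
#' @export
tidy.factor_model <- function(x, threshold = 0.3, ...) {
  as_tibble(x$pattern, rownames = "measure") |>
    tidyr::pivot_longer(-"measure", names_to = "factor",
                        values_to = "loading") |>
    mutate(significant = abs(.data$loading) > threshold,
           communality = x$communalities[.data$measure])
}

#' @rdname tidy.factor_model
#' @method glance factor_model
#' @export
glance.factor_model <- function(x, ...) {
  tibble(
    n = x$n,
    n_variables = ncol(x$correlation),
    n_factors = x$n_factors,
    kmo = x$kmo$overall,
    bartlett_chi2 = x$bartlett$chi2,
    bartlett_df = x$bartlett$df,
    bartlett_p = x$bartlett$p_value,
    variance_explained_prerotation = x$variance_explained_prerotation
  )
}

#' Tidy a factor-correlation result
#'
#' @param x A [factor_factor_correlation()] object.
#' @param ... Unused.
#' @return A tibble: `pupil_factor`, `saccade_factor`, `rho`, `p_value`,
#'   `significant`.
#' @method tidy factor_cor
#' @export
tidy.factor_cor <- function(x, ...) {
  out <- as_tibble(x$rho, rownames = "pupil_factor") |>
    tidyr::pivot_longer(-"pupil_factor", names_to = "saccade_factor",
                        values_to = "rho")
  out$p_value <- as.vector(t(x$p_value))
  out$significant <- as.vector(t(x$significant))
  out
}

#' Tidy a lifespan GAM fit
#'
#' @param x A [fit_gam()] (optionally [derivative_significance()]-annotated)
#'   object.
#' @param ... Unused.
#' @return The grid tibble (age, fit, intervals, derivative columns when
#'   present).
#' @method tidy gam_fit
#' @export
tidy.gam_fit <- function(x, ...) x$grid

#' @rdname tidy.gam_fit
#' @method glance gam_fit
#' @export
glance.gam_fit <- function(x, ...) {
  tibble(
    edf = x$edf,
    n_windows = if (is.null(x$windows)) NA_integer_ else nrow(x$windows),
    derivative_critical = x$derivative_critical %||% NA_real_
  )
}

#' Tidy a sex-difference fit
#'
#' @param x A [sex_difference_window()] object.
#' @param ... Unused.
#' @return The difference-curve grid tibble.
#' @method tidy sex_diff
#' @export
tidy.sex_diff <- function(x, ...) x$grid
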