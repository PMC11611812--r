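#' Fit an age-trajectory GAM
#'
#' Penalized cubic regression spline of an outcome on age
#' (`y ~ s(age, k = 10, bs = "cr")`, Gaussian response, REML smoothness
#' selection), evaluated with pointwise 95% confidence intervals on a grid
#' of 200 equally spaced ages.
#'
#' @param age,y Numeric vectors.
#' @param k Basis dimension (default 10).
#' @param grid_n Grid resolution (default 200).
#' @param grid_range Age range of the grid; default the data range.
#' @param level Confidence level for the pointwise interval.
#' @return An object of class `gam_fit`: the mgcv model plus a `grid`
#'   tibble (`age`, `fit`, `se`, `lo`, `hi`).
#' @export
fit_gam <- function(age, y, k = 10, grid_n = 200, grid_range = NULL,
                    level = 0.95) {
  ok <- is.finite(age) & is.finite(y)
  age <- age[ok]; y <- y[ok]
  check_that(length(age) >= 20, "need at least 20 observations")
  check_that(diff(range(age)) > 1, "degenerate age range")
  dat <- data.frame(age = age, y = y)
  model <- mgcv::gam(y ~ s(age, k = k, bs = "cr"), data = dat,
                     method = "REML")
  rng <- grid_range %||% range(age)
  grid_age <- seq(rng[1], rng[2], length.out = grid_n)
  pr <- predict(model, newdata = data.frame(age = grid_age), se.fit = TRUE)
  z <- qnorm(1 - (1 - level) / 2)
  structure(list(
    model = model,
    edf = sum(model$edf),
    grid = tibble(age = grid_age, fit = as.numeric(pr$fit),
                  se = as.numeric(pr$se.fit),
                  lo = as.numeric(pr$fit - z * pr$se.fit),
                  hi = as.numeric(pr$fit + z * pr$se.fit)),
    k = k, level = level
  ), class = "gam_fit")
}

#' Significant periods of change from the GAM derivative
#'
#' The fitted smooth's first derivative is estimated by central finite
#' differences (`eps` years) of the linear-predictor matrix, and its
#' confidence band from draws of the spline coefficients' posterior. With
#' `simultaneous = TRUE` (default) the band has simultaneous 95% coverage
#' across the whole grid (the max-statistic critical value over the draws),
#' which controls the family-wise error of window detection; pointwise
#' bands are available for comparison. Significant periods are maximal grid
#' runs where the band excludes zero.
#'
#' @param fit A [fit_gam()] object.
#' @param eps Finite-difference step, years (default 0.1).
#' @param n_draws Posterior draws (default 10,000).
#' @param level Band level.
#' @param simultaneous Simultaneous (default) or pointwise band.
#' @param seed Seed for the posterior draws.
#' @return The `gam_fit` with grid columns `deriv`, `dse`, `dlo`, `dhi`,
#'   `significant`, and a `windows` tibble (`age_lo`, `age_hi`).
#' @export
derivative_significance <- function(fit, eps = 0.1, n_draws = 10000,
                                    level = 0.95, simultaneous = TRUE,
                                    seed = 1L) {
  check_that(inherits(fit, "gam_fit"), "`fit` must be a gam_fit")
  model <- fit$model
  g <- fit$grid$age
  X1 <- predict(model, newdata = data.frame(age = g + eps),
                type = "lpmatrix")
  X0 <- predict(model, newdata = data.frame(age = g - eps),
                type = "lpmatrix")
  Xd <- (X1 - X0) / (2 * eps)
  b <- coef(model)
  Vp <- vcov(model)
  d_hat <- as.numeric(Xd %*% b)
  d_se <- sqrt(pmax(rowSums((Xd %*% Vp) * Xd), 1e-300))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  crit <- qnorm(1 - (1 - level) / 2)
  if (simultaneous) {
    B <- mgcv::rmvn(n_draws, b, Vp)
    dev <- abs(Xd %*% t(B) - d_hat) / d_se
    maxdev <- apply(dev, 2, max)
    crit <- unname(quantile(maxdev, level))
  }
  grid <- fit$grid
  grid$deriv <- d_hat
  grid$dse <- d_se
  grid$dlo <- d_hat - crit * d_se
  grid$dhi <- d_hat + crit * d_se
  grid$significant <- grid$dlo > 0 | grid$dhi < 0
  fit$grid <- grid
  fit$derivative_critical <- crit
  fit$windows <- significant_windows(grid$age, grid$significant)
  fit
}

significant_windows <- function(age, significant) {
  runs <- true_runs(significant)
  if (!runs$n) return(tibble(age_lo = numeric(), age_hi = numeric()))
  tibble(age_lo = age[runs$start], age_hi = age[runs$end])
}

#' Per-condition smoothing-spline age trajectories
#'
#' Cross-validated cubic smoothing splines of a measure on age, fitted
#' separately per task condition; for qualitative display only (no
#' inference is attached).
#'
#' @param data Tibble with columns `age`, `value` and (optionally)
#'   `condition`.
#' @param grid_n Evaluation grid resolution.
#' @return Tibble (`condition`, `age`, `fit`).
#' @export
smoothing_spline_fit <- function(data, grid_n = 200) {
  if (!"condition" %in% names(data)) data$condition <- "ALL"
  data |>
    filter(is.finite(.data$age), is.finite(.data$value)) |>
    group_by(.data$condition) |>
    dplyr::group_modify(function(d, key) {
      sp <- smooth.spline(d$age, d$value)
      g <- seq(min(d$age), max(d$age), length.out = grid_n)
      tibble(age = g, fit = predict(sp, g)$y)
    }) |>
    ungroup()
}

#' Sex-difference trajectory and significant windows
#'
#' Fits a GAM with a shared age smooth plus a sex-specific difference
#' smooth (ordered-factor construction:
#' `y ~ sex + s(age) + s(age, by = ordered(sex))`), forms the female-minus-
#' male difference curve on the age grid, and finds the ages where its 95%
#' simultaneous confidence band (posterior max-statistic, as in
#' [derivative_significance()]) excludes zero.
#'
#' @param age,y Numeric vectors.
#' @param sex Character/factor vector (`"F"`/`"M"`).
#' @param k Basis dimension.
#' @param grid_n Grid resolution.
#' @param n_draws Posterior draws for the simultaneous band.
#' @param level Band level.
#' @param simultaneous Simultaneous (default) or pointwise band.
#' @param seed Seed for the draws.
#' @return An object of class `sex_diff`: `grid` tibble (`age`, `diff`,
#'   `se`, `lo`, `hi`, `significant`) and `windows`.
#' @export
sex_difference_window <- function(age, y, sex, k = 10, grid_n = 200,
                                  n_draws = 10000, level = 0.95,
                                  simultaneous = TRUE, seed = 1L) {
  ok <- is.finite(age) & is.finite(y) & !is.na(sex)
  age <- age[ok]; y <- y[ok]; sex <- as.character(sex)[ok]
  check_that(length(unique(sex)) == 2,
             "both sexes must be present to estimate a sex difference")
  dat <- data.frame(age = age, y = y,
                    sex = factor(sex, levels = c("M", "F")),
                    osex = ordered(sex, levels = c("M", "F")))
  model <- mgcv::gam(y ~ sex + s(age, k = k, bs = "cr") +
                       s(age, by = osex, k = k, bs = "cr"),
                     data = dat, method = "REML")
  g <- seq(min(age), max(age), length.out = grid_n)
  newF <- data.frame(age = g, sex = factor("F", levels = c("M", "F")),
                     osex = ordered("F", levels = c("M", "F")))
  newM <- data.frame(age = g, sex = factor("M", levels = c("M", "F")),
                     osex = ordered("M", levels = c("M", "F")))
  Xd <- predict(model, newdata = newF, type = "lpmatrix") -
    predict(model, newdata = newM, type = "lpmatrix")
  b <- coef(model)
  Vp <- vcov(model)
  d_hat <- as.numeric(Xd %*% b)
  d_se <- sqrt(pmax(rowSums((Xd %*% Vp) * Xd), 1e-300))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  crit <- qnorm(1 - (1 - level) / 2)
  if (simultaneous) {
    B <- mgcv::rmvn(n_draws, b, Vp)
    dev <- abs(Xd %*% t(B) - d_hat) / d_se
    crit <- unname(quantile(apply(dev, 2, max), level))
  }
  grid <- tibble(age = g, diff = d_hat, se = d_se,
                 lo = d_hat - crit * d_se, hi = d_hat + crit * d_se)
  grid$significant <- grid$lo > 0 | grid$hi < 0
  structure(list(model = model, grid = grid,
                 windows = significant_windows(g, grid$significant),
                 critical = crit),
            class = "sex_diff")
}

default_age_group_breaks <- function() {
  c(5, 8, 12, 16, 20, 29, 39, 49, 59, 69, 83, 93)
}

#' Assign participants to discrete age groups
#'
#' Eleven lifespan groups by default (5-8, 9-12, 13-16, 17-20, 21-29,
#' 30-39, 40-49, 50-59, 60-69, 70-83, 84-93 years), used for the
#' group-averaged trace displays. Boundary ages belong to the lower group
#' (closed-upper convention).
#'
#' @param ages Numeric vector of ages.
#' @param breaks Increasing vector of group upper bounds (first element is
#'   the overall lower bound); default [the 11-group scheme].
#' @return Factor of group labels like `"5-8"`.
#' @export
bin_age_groups <- function(ages, breaks = default_age_group_breaks()) {
  check_that(all(ages >= breaks[1] & ages <= breaks[length(breaks)]),
             sprintf("ages must lie within [%g, %g]", breaks[1],
                     breaks[length(breaks)]))
  labels <- paste0(c(breaks[1], floor(breaks[-c(1, length(breaks))]) + 1),
                   "-", breaks[-1])
  cut(ages, breaks = breaks, labels = labels, include.lowest = TRUE,
      right = TRUE)
}
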