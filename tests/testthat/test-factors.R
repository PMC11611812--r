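test_that("correlation matrices are complete-case, symmetric, guarded", {
  set.seed(1)
  x <- tibble::tibble(a = rnorm(50), b = rnorm(50))
  x$c <- x$a
  R <- correlation_matrix(x)
  expect_equal(R["a", "c"], 1)
  expect_equal(R, t(R))
  # monotone transforms leave Spearman untouched
  y <- tibble::tibble(a = x$a, b = exp(x$b))
  expect_equal(correlation_matrix(x[1:2], "spearman"),
               correlation_matrix(y, "spearman"),
               ignore_attr = TRUE)
  x$z <- 1
  expect_error(correlation_matrix(x), "zero-variance.*z")
})

test_that("KMO equals 1/2 for two variables and ranks structure highly", {
  R2 <- matrix(c(1, 0.4, 0.4, 1), 2)
  expect_equal(kmo(R2)$overall, 0.5)
  # block-diagonal 2-factor structure, loading 0.8, 3 variables per factor
  L <- matrix(0, 6, 2); L[1:3, 1] <- 0.8; L[4:6, 2] <- 0.8
  Rb <- L %*% t(L); diag(Rb) <- 1
  k <- kmo(Rb)
  expect_gt(k$overall, 0.6)
  expect_length(k$per_variable, 6)
  # near-identity with only spurious correlations: inadequate sampling
  set.seed(14)
  E <- matrix(rnorm(36, 0, 0.04), 6)
  Ri <- diag(6) + (E + t(E)) / 2; diag(Ri) <- 1
  expect_lt(kmo(Ri)$overall, 0.5)
})

test_that("Bartlett sphericity matches its closed form", {
  ident <- bartlett_sphericity(diag(5), 100)
  expect_equal(ident$chi2, 0)
  expect_equal(ident$p_value, 1)
  expect_equal(bartlett_sphericity(diag(14), 100)$df, 91)
  R3 <- matrix(c(1, .3, .2, .3, 1, .5, .2, .5, 1), 3)
  out <- bartlett_sphericity(R3, 40)
  # independent hand computation of the statistic
  det3 <- 1 * (1 - .25) - .3 * (.3 - .1) + .2 * (.15 - .2)
  expect_equal(out$chi2, -(40 - 1 - (2 * 3 + 5) / 6) * log(det3),
               tolerance = 1e-10)
})

test_that("principal axis factoring recovers an exact one-factor model", {
  lam <- c(0.8, 0.7, 0.6)
  R <- lam %o% lam; diag(R) <- 1
  paf <- principal_axis_factoring(R, 1, tol = 1e-7, max_iter = 1000)
  expect_equal(abs(drop(paf$loadings)), lam, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(choose_n_factors(R), 1)
  # identity input: no common variance
  pid <- principal_axis_factoring(diag(4), 1)
  expect_lt(max(abs(pid$loadings)), 1e-6)
  expect_equal(choose_n_factors(diag(6)), 0)
})

test_that("PAF agrees with brute-force least-squares factoring at p = 4", {
  lam <- c(0.85, 0.7, 0.55, 0.4)
  R <- lam %o% lam; diag(R) <- 1
  paf <- principal_axis_factoring(R, 1, tol = 1e-8, max_iter = 2000)
  # independent oracle: minimise ||R - ll' - diag(psi)||_F numerically
  obj <- function(par) {
    l <- par[1:4]
    fit <- l %o% l
    diag(fit) <- diag(fit) + par[5:8]^2
    sum((R - fit)^2)
  }
  opt <- optim(c(rep(0.5, 4), rep(0.5, 4)), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(abs(drop(paf$loadings)), abs(opt$par[1:4]), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("oblimin preserves communalities and resolves simple structure", {
  L <- matrix(0, 6, 2)
  L[1:3, 1] <- c(0.8, 0.75, 0.7); L[4:6, 2] <- c(0.8, 0.7, 0.65)
  R <- L %*% t(L); diag(R) <- 1
  paf <- principal_axis_factoring(R, 2, tol = 1e-7, max_iter = 1000)
  rot <- oblimin_rotate(paf$loadings)
  h_before <- rowSums(paf$loadings^2)
  h_after <- diag(rot$pattern %*% rot$phi %*% t(rot$pattern))
  expect_lt(max(abs(h_before - h_after)), 1e-8)
  m <- match_factors(rot$pattern, L)
  expect_true(all(m$congruence > 0.999))
  expect_lt(abs(rot$phi[1, 2]), 0.05)
  # single factor: identity rotation
  one <- oblimin_rotate(paf$loadings[, 1, drop = FALSE])
  expect_equal(one$pattern, paf$loadings[, 1, drop = FALSE])
})

test_that("PAF plus oblimin reproduces a noiseless model-implied matrix", {
  L <- pupil_factor_loadings()
  R <- L %*% t(L); diag(R) <- 1
  paf <- principal_axis_factoring(R, 3, tol = 1e-7, max_iter = 1000)
  rot <- oblimin_rotate(paf$loadings)
  recon <- rot$pattern %*% rot$phi %*% t(rot$pattern) +
    diag(1 - paf$communalities)
  expect_lt(max(abs(R - recon)), 1e-3)
})

test_that("regression scores track the latent factors", {
  # well-determined structure (4+ indicators per factor)
  L <- matrix(0, 14, 3)
  L[1:5, 1] <- 0.8; L[6:10, 2] <- 0.8; L[11:14, 3] <- 0.8
  sim <- simulate_measure_rows(800, loadings = L, seed = 21)
  fm <- fit_factor_model(sim, n_factors = 3)
  sc <- factor_scores(fm)
  expect_lt(max(abs(colMeans(sc))), 1e-10)
  lat <- attr(sim, "latent_scores")
  best <- apply(abs(cor(sc, lat)), 1, max)
  expect_true(all(best > 0.9))
  # a doublet factor is less determinate but still tracked
  sacc <- generate_saccade_measure_table(800, seed = 22)
  fms <- fit_factor_model(sacc, n_factors = 4)
  scs <- factor_scores(fms)
  bests <- apply(abs(cor(scs, attr(sacc, "latent_scores"))), 1, max)
  expect_true(all(bests > 0.7))
})

test_that("loading significance uses a strict 0.3 threshold", {
  pat <- matrix(c(0.30, -0.31, 0, 0.8), 2)
  mask <- significant_loadings(pat)
  expect_equal(as.vector(mask), c(FALSE, TRUE, FALSE, TRUE))
  expect_false(any(significant_loadings(matrix(0, 3, 2))))
})

test_that("factor-factor correlation flags only Bonferroni survivors", {
  set.seed(3)
  x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, paste0("P", 1:3)))
  y <- cbind(x[, 1], matrix(rnorm(300), 100, 3))
  colnames(y) <- paste0("S", 1:4)
  fc <- factor_factor_correlation(x, y)
  expect_equal(fc$m, 12)
  expect_equal(fc$rho["P1", "S1"], 1)
  expect_true(fc$significant["P1", "S1"])
  expect_error(factor_factor_correlation(x[1:5, ], y[1:5, ]), "10")
  td <- tidy(fc)
  expect_equal(nrow(td), 12)
})

test_that("the full factor model object is coherent", {
  sim <- simulate_measure_rows(300, seed = 8)
  fm <- fit_factor_model(sim)
  expect_s3_class(fm, "factor_model")
  expect_equal(fm$bartlett$df, 14 * 13 / 2)
  expect_true(all(fm$communalities >= 0 & fm$communalities <= 1))
  expect_lt(max(abs(fm$pattern)), 1.05)
  g <- glance(fm)
  expect_equal(g$n_variables, 14)
  td <- tidy(fm)
  expect_equal(nrow(td), 14 * fm$n_factors)
})
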