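#' Correlation matrix of a measure table
#'
#' Complete-case Pearson or Spearman correlations with a unit diagonal.
#'
#' @param table Data frame of numeric measure columns (an `id` column, if
#'   present, is dropped).
#' @param method `"pearson"` or `"spearman"`.
#' @return Symmetric correlation matrix.
#' @export
correlation_matrix <- function(table, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.data.frame(table)
  x$id <- NULL
  check_that(all(vapply(x, is.numeric, logical(1))),
             "all measure columns must be numeric")
  x <- x[complete.cases(x), , drop = FALSE]
  check_that(nrow(x) >= 3, "need at least 3 complete rows")
  sds <- vapply(x, sd, numeric(1))
  if (any(sds == 0)) {
    abort(sprintf("zero-variance column(s): %s",
                  paste(names(x)[sds == 0], collapse = ", ")), call = NULL)
  }
  R <- cor(x, method = method)
  diag(R) <- 1
  R
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Compares the observed correlations with the anti-image partial
#' correlations: `KMO = sum(r^2) / (sum(r^2) + sum(q^2))` over off-diagonal
#' entries, where `q` are the partial correlations given all other
#' variables. Values near 1 indicate that factoring is sensible; below 0.5
#' is conventionally inadequate.
#'
#' @param R Correlation matrix.
#' @return A list: `overall`, `per_variable` (named vector).
#' @export
kmo <- function(R) {
  R <- as.matrix(R)
  inv <- tryCatch(solve(R), error = function(e) {
    abort("correlation matrix is singular; consider removing collinear variables",
          call = NULL)
  })
  d <- 1 / sqrt(diag(inv))
  Q <- -inv * outer(d, d)   # anti-image partial correlations
  diag(Q) <- 0
  R0 <- R; diag(R0) <- 0
  overall <- sum(R0^2) / (sum(R0^2) + sum(Q^2))
  per_var <- colSums(R0^2) / (colSums(R0^2) + colSums(Q^2))
  names(per_var) <- colnames(R)
  list(overall = overall, per_variable = per_var)
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix is the identity:
#' `chi2 = -(n - 1 - (2p + 5)/6) * ln det(R)` with `p(p-1)/2` degrees of
#' freedom. For the 14-variable pupil table the test has 91 df.
#'
#' @param R Correlation matrix.
#' @param n Number of observations behind `R`.
#' @return A list: `chi2`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(R, n) {
  p <- ncol(R)
  check_that(n > p, "`n` must exceed the number of variables")
  dt <- det(as.matrix(R))
  check_that(dt > 0, "correlation matrix must have positive determinant")
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(dt)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df, p_value = stats::pchisq(chi2, df,
                                                     lower.tail = FALSE))
}

#' Number of factors by the Kaiser criterion
#'
#' Counts eigenvalues of the full (unreduced) correlation matrix strictly
#' greater than 1.
#'
#' @param R Correlation matrix.
#' @return Integer factor count.
#' @export
choose_n_factors <- function(R) {
  sum(eigen(as.matrix(R), symmetric = TRUE, only.values = TRUE)$values > 1)
}

smc_communalities <- function(R) {
  inv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(inv)) {
    apply(abs(R - diag(diag(R))), 2, max)
  } else {
    1 - 1 / diag(inv)
  }
}

#' Principal axis factoring
#'
#' Iterated principal-axis extraction: the correlation matrix's diagonal is
#' replaced by communality estimates (initialised at the squared multiple
#' correlations), the reduced matrix is eigendecomposed, loadings are the
#' top-`n_factors` eigenvectors scaled by the square roots of their
#' eigenvalues, and the communalities are updated from the loadings until
#' the largest communality change falls below `tol`. Heywood cases
#' (communality > 1) are clamped at 0.999 with a warning.
#'
#' @param R Correlation matrix.
#' @param n_factors Number of factors to extract.
#' @param max_iter Iteration cap (default 1000; Heywood drift on
#'   doublet factors can take a few hundred iterations to settle).
#' @param tol Convergence tolerance on communalities (default 1e-3, the
#'   SPSS convention; doublet factors can drift toward Heywood cases under
#'   much tighter tolerances).
#' @return A list: `loadings` (p x k, unrotated), `communalities`,
#'   `iterations`.
#' @export
principal_axis_factoring <- function(R, n_factors, max_iter = 1000,
                                     tol = 1e-3) {
  R <- as.matrix(R)
  p <- ncol(R)
  check_that(n_factors >= 1 && n_factors < p,
             "`n_factors` must be in [1, p)")
  h2 <- pmin(pmax(smc_communalities(R), 0), 0.999)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    Rh <- R
    diag(Rh) <- h2
    e <- eigen(Rh, symmetric = TRUE)
    lam <- pmax(e$values[seq_len(n_factors)], 0)
    L <- e$vectors[, seq_len(n_factors), drop = FALSE] %*%
      diag(sqrt(lam), n_factors)
    h2_new <- rowSums(L^2)
    if (any(h2_new > 1)) {
      warn("Heywood case: communality exceeded 1; clamped at 0.999")
      h2_new <- pmin(h2_new, 0.999)
    }
    delta <- max(abs(h2_new - h2))
    trace <- c(trace, delta)
    h2 <- h2_new
    if (delta < tol) {
      dimnames(L) <- list(colnames(R), paste0("F", seq_len(n_factors)))
      names(h2) <- colnames(R)
      return(list(loadings = L, communalities = h2, iterations = it))
    }
  }
  abort(paste0("principal axis factoring did not converge in ", max_iter,
               " iterations; last communality changes: ",
               paste(signif(tail(trace, 5), 3), collapse = ", ")),
        call = NULL)
}

vgq_oblimin <- function(L, gamma = 0) {
  k <- ncol(L)
  N <- matrix(1, k, k) - diag(k)
  X <- L^2 %*% N
  if (gamma != 0) {
    p <- nrow(L)
    X <- (diag(p) - matrix(gamma / p, p, p)) %*% X
  }
  list(f = sum(L^2 * X) / 4, Gq = L * X)
}

#' Direct oblimin rotation
#'
#' Oblique rotation of an unrotated loading matrix by gradient-projection
#' minimisation of the direct-oblimin criterion; `gamma = 0` is direct
#' quartimin (the SPSS default). With a single factor the input is returned
#' unchanged. Communalities (diagonal of `P Phi P'`) are invariant under
#' the rotation.
#'
#' @param loadings Unrotated p x k loading matrix.
#' @param gamma Oblimin parameter (default 0).
#' @param max_iter Iteration cap (default 1000).
#' @param eps Gradient-norm convergence tolerance.
#' @return A list: `pattern` (p x k pattern matrix), `phi` (k x k factor
#'   correlation matrix), `iterations`.
#' @export
oblimin_rotate <- function(loadings, gamma = 0, max_iter = 1000, eps = 1e-6) {
  A <- as.matrix(loadings)
  k <- ncol(A)
  if (k == 1) {
    return(list(pattern = A, phi = matrix(1, 1, 1), iterations = 0L))
  }
  Tmat <- diag(k)
  al <- 1
  L <- A %*% t(solve(Tmat))
  vg <- vgq_oblimin(L, gamma)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% solve(Tmat))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), k)
    s <- sqrt(sum(Gp^2))
    if (s < eps) { converged <- TRUE; break }
    al <- 2 * al
    for (i in 0:10) {
      X <- Tmat - al * Gp
      v <- 1 / sqrt(colSums(X^2))
      Tt <- X %*% diag(v, k)
      L <- A %*% t(solve(Tt))
      vgt <- vgq_oblimin(L, gamma)
      if (vgt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    f <- vgt$f
    G <- -t(t(L) %*% vgt$Gq %*% solve(Tmat))
  }
  if (!converged) {
    abort(sprintf("oblimin rotation did not converge in %d iterations",
                  max_iter), call = NULL)
  }
  pattern <- A %*% t(solve(Tmat))
  phi <- t(Tmat) %*% Tmat
  dimnames(pattern) <- dimnames(A)
  dimnames(phi) <- list(colnames(A), colnames(A))
  list(pattern = pattern, phi = phi, iterations = iter)
}

#' Regression (Thurstone) factor scores
#'
#' `scores = Z R^{-1} S` where `Z` are the standardized data and
#' `S = P Phi` is the structure matrix.
#'
#' @param model A fitted [fit_factor_model()] object.
#' @param table Data on the model's variables (defaults to the data the
#'   model was fitted on).
#' @return n x k matrix of factor scores.
#' @export
factor_scores <- function(model, table = NULL) {
  x <- as.data.frame(table %||% model$data)
  ids <- x$id
  x$id <- NULL
  x <- x[, rownames(model$pattern), drop = FALSE]
  cc <- complete.cases(x)
  Z <- scale(as.matrix(x[cc, , drop = FALSE]))
  S <- model$pattern %*% model$phi
  W <- tryCatch(solve(model$correlation, S), error = function(e) {
    abort("correlation matrix is singular; cannot compute regression scores",
          call = NULL)
  })
  out <- Z %*% W
  colnames(out) <- colnames(model$pattern)
  if (!is.null(ids)) rownames(out) <- ids[cc]
  out
}

#' Threshold a pattern matrix
#'
#' Loadings with absolute value strictly greater than `threshold` (default
#' 0.3) are flagged as significant.
#'
#' @param pattern Pattern (or loading) matrix.
#' @param threshold Absolute-loading threshold.
#' @return Logical matrix of the same shape.
#' @export
significant_loadings <- function(pattern, threshold = 0.3) {
  abs(as.matrix(pattern)) > threshold
}

#' Fit the full exploratory factor model
#'
#' Complete-case correlation matrix (Pearson by default, the conventional
#' input for principal-axis factoring; Spearman available for display and
#' sensitivity), KMO and Bartlett adequacy checks, Kaiser eigenvalue
#' retention (strictly > 1) unless `n_factors` is given, iterated
#' principal-axis extraction, direct-oblimin rotation and regression factor
#' scores.
#'
#' @param data Data frame of measures (optional `id` column kept for score
#'   row names).
#' @param n_factors Number of factors; default: Kaiser criterion.
#' @param cor_method Correlation for the factoring input.
#' @param gamma Oblimin parameter.
#' @return An object of class `factor_model`.
#' @export
fit_factor_model <- function(data, n_factors = NULL,
                             cor_method = c("pearson", "spearman"),
                             gamma = 0) {
  cor_method <- match.arg(cor_method)
  x <- as.data.frame(data)
  ids <- x$id
  x$id <- NULL
  cc <- complete.cases(x)
  n <- sum(cc)
  R <- correlation_matrix(x, method = cor_method)
  adequacy <- kmo(R)
  if (adequacy$overall < 0.5) {
    warn(sprintf("overall KMO = %.3f: sampling adequacy is conventionally inadequate",
                 adequacy$overall))
  }
  bart <- bartlett_sphericity(R, n)
  eigenvalues <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  k <- n_factors %||% choose_n_factors(R)
  check_that(k >= 1, "Kaiser criterion retained no factors; supply n_factors")
  paf <- principal_axis_factoring(R, k)
  rot <- oblimin_rotate(paf$loadings, gamma = gamma)
  structure(list(
    correlation = R,
    cor_method = cor_method,
    n = n,
    kmo = adequacy,
    bartlett = bart,
    eigenvalues = eigenvalues,
    n_factors = k,
    unrotated = paf$loadings,
    pattern = rot$pattern,
    phi = rot$phi,
    communalities = paf$communalities,
    variance_explained_prerotation = 100 * sum(eigenvalues[seq_len(k)]) /
      ncol(R),
    data = tibble(id = ids %||% as.character(seq_len(nrow(x))), !!!x)
  ), class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("Factor model: %d variables, %d factors (%s correlations, n = %d)\n",
              ncol(x$correlation), x$n_factors, x$cor_method, x$n))
  cat(sprintf("KMO = %.3f; Bartlett chi2(%d) = %.1f, p = %.3g\n",
              x$kmo$overall, x$bartlett$df, x$bartlett$chi2,
              x$bartlett$p_value))
  cat(sprintf("Variance explained before rotation: %.2f%%\n",
              x$variance_explained_prerotation))
  print(round(x$pattern, 3))
  invisible(x)
}

#' Correlate two sets of factor scores
#'
#' Pairwise Spearman correlations between every pupil factor and every
#' saccade factor, with Bonferroni control of the family of
#' `k1 * k2` tests.
#'
#' @param x,y Score matrices (rows matched by rownames when present,
#'   otherwise by position).
#' @param alpha Family-wise significance level.
#' @return An object of class `factor_cor`: `rho`, `p_value`,
#'   `significant`, `m` (number of tests), `n` (complete cases).
#' @export
factor_factor_correlation <- function(x, y, alpha = 0.05) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!is.null(rownames(x)) && !is.null(rownames(y))) {
    common <- intersect(rownames(x), rownames(y))
    x <- x[common, , drop = FALSE]
    y <- y[common, , drop = FALSE]
  }
  check_that(nrow(x) == nrow(y), "score matrices must have matched rows")
  cc <- complete.cases(x) & complete.cases(y)
  x <- x[cc, , drop = FALSE]; y <- y[cc, , drop = FALSE]
  check_that(nrow(x) >= 10, "need at least 10 complete cases")
  k1 <- ncol(x); k2 <- ncol(y)
  rho <- matrix(NA_real_, k1, k2,
                dimnames = list(colnames(x), colnames(y)))
  pv <- rho
  for (i in seq_len(k1)) {
    for (j in seq_len(k2)) {
      ct <- suppressWarnings(cor.test(x[, i], y[, j], method = "spearman",
                                      exact = FALSE))
      rho[i, j] <- unname(ct$estimate)
      pv[i, j] <- ct$p.value
    }
  }
  m <- k1 * k2
  structure(list(rho = rho, p_value = pv,
                 significant = pv < alpha / m, m = m, n = nrow(x),
                 alpha = alpha),
            class = "factor_cor")
}

#' Tucker congruence between loading vectors
#'
#' Cosine similarity `sum(a b) / sqrt(sum(a^2) sum(b^2))`, the standard
#' index for matching recovered factors to their generating loadings.
#'
#' @param a,b Numeric vectors or matrices (columns compared pairwise when
#'   both are matrices of equal width).
#' @return Scalar (vectors) or vector of per-column congruences (matrices).
#' @export
tucker_congruence <- function(a, b) {
  if (is.matrix(a) && is.matrix(b)) {
    vapply(seq_len(ncol(a)),
           function(j) tucker_congruence(a[, j], b[, j]), numeric(1))
  } else {
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
}

#' Match estimated factors to reference factors
#'
#' Greedy assignment maximising absolute Tucker congruence, with sign
#' alignment, for factor-recovery checks.
#'
#' @param est Estimated p x k loading (pattern) matrix.
#' @param ref Reference p x k loading matrix.
#' @return A list: `matched` (columns of `est` permuted and sign-aligned to
#'   `ref`), `congruence` (per reference factor), `order`, `signs`.
#' @export
match_factors <- function(est, ref) {
  est <- as.matrix(est); ref <- as.matrix(ref)
  k <- ncol(ref)
  C <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) C[i, j] <- tucker_congruence(ref[, i], est[, j])
  }
  ord <- integer(k); sgn <- numeric(k)
  avail <- rep(TRUE, k)
  absC <- abs(C)
  for (step in seq_len(k)) {
    # largest remaining |congruence| among unassigned pairs
    best <- -Inf; bi <- bj <- NA_integer_
    for (i in seq_len(k)) {
      if (ord[i] != 0) next
      for (j in seq_len(k)) {
        if (!avail[j]) next
        if (absC[i, j] > best) { best <- absC[i, j]; bi <- i; bj <- j }
      }
    }
    ord[bi] <- bj
    sgn[bi] <- sign(C[bi, bj])
    avail[bj] <- FALSE
  }
  matched <- est[, ord, drop = FALSE] %*% diag(sgn, k)
  colnames(matched) <- colnames(ref)
  cong <- vapply(seq_len(k),
                 function(i) tucker_congruence(ref[, i], matched[, i]),
                 numeric(1))
  list(matched = matched, congruence = cong, order = ord, signs = sgn)
}
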