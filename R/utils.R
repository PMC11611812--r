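#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble new_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join across n
#' @importFrom stats median sd var cor cor.test wilcox.test pt qnorm quantile
#'   rnorm runif rbinom setNames complete.cases coef vcov predict approx
#'   smooth.spline p.adjust
#' @importFrom utils head tail
NULL

# internal: stop unless condition holds, naming the offending field
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg, call = NULL)
  invisible(TRUE)
}

# maximal runs of TRUE in a logical vector -> list(start, end) of indices
true_runs <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  list(start = starts[keep], end = ends[keep], n = sum(keep))
}

# centered moving average over +/- k samples that ignores NA entries and
# shrinks at the edges: mean of available values in the window
boxcar_mean <- function(x, k) {
  n <- length(x)
  ok <- !is.na(x)
  xv <- ifelse(ok, x, 0)
  cs <- c(0, cumsum(xv))
  cn <- c(0, cumsum(as.numeric(ok)))
  i <- seq_len(n)
  lo <- pmax(i - k, 1L)
  hi <- pmin(i + k, n)
  tot <- cs[hi + 1L] - cs[lo]
  cnt <- cn[hi + 1L] - cn[lo]
  out <- ifelse(cnt > 0, tot / cnt, NA_real_)
  out
}

# rolling sum over windows of length w starting at each index (length n-w+1)
roll_sum <- function(x, w) {
  cs <- c(0, cumsum(x))
  n <- length(x)
  if (n < w) return(numeric(0))
  cs[(w + 1L):(n + 1L)] - cs[1:(n - w + 1L)]
}

derive_seed <- function(seed, offset) {
  (as.integer(seed) * 7919L + as.integer(offset)) %% 2147483629L
}
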