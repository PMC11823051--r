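# Distance covariance / correlation estimators.  All use the biased
# V-statistic (double-centered) form, so every quadratic form stays
# nonnegative and can serve as an optimization objective downstream.

dist_of <- function(x) {
  x <- as_obs_matrix(x)
  if (ncol(x) == 1L) cpp_dist_vec(drop(x)) else cpp_dist_mat(x)
}

#' Sample distance correlation
#'
#' Distance correlation of two samples (scalar or vector observations),
#' V-statistic form.  It is zero if and only if the variables are
#' empirically "distance uncorrelated"; at the population level, zero iff
#' independent.  By convention a constant variable has distance
#' correlation zero with anything.
#'
#' @param x,y numeric vectors, or matrices with one observation per row.
#' @return A scalar in \[0, 1\].
#' @examples
#' dcor(1:5, c(1, 0, 3, 2, 5))
#' @export
dcor <- function(x, y) {
  x <- as_obs_matrix(x, "x"); y <- as_obs_matrix(y, "y")
  n <- nrow(x)
  if (nrow(y) != n) stop("x and y must have the same number of rows")
  if (n < 4L) stop("invalid sample: distance correlation needs n >= 4")
  wdcor(x, y, rep(1, n))
}

#' Weighted squared distance covariance
#'
#' The quadratic form \eqn{n^{-2} \sum_{ij} w_i w_j A_{ij} B_{ij}} over the
#' (unweighted) double-centered distance matrices of `x` and `y`.  With
#' uniform weights this is the ordinary squared distance covariance; as a
#' function of `w` it is a positive semidefinite quadratic form (centered
#' Euclidean distance matrices are negative semidefinite, so their
#' elementwise product is PSD by the Schur product theorem), which is what
#' makes it usable as a balance objective.
#'
#' @inheritParams dcor
#' @param w weight vector, nonnegative, summing to the sample size.
#' @return A nonnegative scalar.
#' @export
wdcov_sq <- function(x, y, w) {
  x <- as_obs_matrix(x, "x"); y <- as_obs_matrix(y, "y")
  if (nrow(x) != nrow(y)) stop("x and y must have the same number of rows")
  check_weights(w, nrow(x))
  A <- cpp_dcenter(dist_of(x))
  B <- cpp_dcenter(dist_of(y))
  max(cpp_wstats(A, B, w)[1], 0)
}

#' Weighted distance correlation
#'
#' Weighted distance covariance normalized by the geometric mean of the
#' weighted distance variances; zero when either variable is degenerate
#' under the weights.
#'
#' @inheritParams wdcov_sq
#' @return A scalar in \[0, 1\].
#' @export
wdcor <- function(x, y, w) {
  x <- as_obs_matrix(x, "x"); y <- as_obs_matrix(y, "y")
  if (nrow(x) != nrow(y)) stop("x and y must have the same number of rows")
  check_weights(w, nrow(x))
  A <- cpp_dcenter(dist_of(x))
  B <- cpp_dcenter(dist_of(y))
  s <- cpp_wstats(A, B, w)
  den <- sqrt(s[2] * s[3])
  if (!is.finite(den) || den <= 1e-14) return(0)
  r2 <- s[1] / den
  if (r2 <= 0) 0 else sqrt(min(r2, 1))
}

# Gaussian kernel weight matrix for conditional statistics: one column per
# evaluation point, each column rescaled to sum to n.
cdcor_kernel_weights <- function(t, eval_points, bw) {
  n <- length(t)
  W <- vapply(eval_points, function(t0) {
    k <- dnorm((t - t0) / bw)
    s <- sum(k)
    if (s <= 0) rep(1, n) else n * k / s
  }, numeric(n))
  W
}

cdcor_eval_points <- function(t, n_eval) {
  n_eval <- min(n_eval, length(t))
  if (n_eval >= length(t)) return(sort(t))
  unname(quantile(t, probs = seq(0.05, 0.95, length.out = n_eval),
                  type = 7))
}

#' Conditional distance correlation (kernel-smoothed)
#'
#' Estimates the distance correlation between `z` and `y` given `t` by
#' computing, at each of a set of evaluation points along `t`, a locally
#' weighted distance correlation with Nadaraya-Watson Gaussian kernel
#' weights (weighted double centering), and averaging over evaluation
#' points.  Bandwidth defaults to Silverman's rule on `t`
#' ([stats::bw.nrd0()]).  If `t` is constant the statistic degenerates and
#' the unconditional [dcor()] is returned with a warning.
#'
#' @param z,y numeric vectors (length n).
#' @param t conditioning variable (length n).
#' @param bw kernel bandwidth; default Silverman's rule on `t`.
#' @param n_eval number of quantile-spaced evaluation points (capped at n).
#' @return A scalar in \[0, 1\]; 0 when `z` or `y` is constant.
#' @export
cdcor <- function(z, y, t, bw = NULL, n_eval = 20) {
  check_numeric(z, "z"); check_numeric(y, "y"); check_numeric(t, "t")
  n <- length(t)
  if (length(z) != n || length(y) != n)
    stop("z, y, t must have equal length")
  if (n < 10L) stop("invalid sample: conditional dcor needs n >= 10")
  if (sd(t) == 0) {
    warning("conditioning variable is constant; ",
            "falling back to unconditional distance correlation")
    return(dcor(z, y))
  }
  drop(cdcor_all(matrix(z, ncol = 1), y, t, bw = bw, n_eval = n_eval))
}

# Vectorized conditional dcor over columns of Z (shared y, t, kernel).
cdcor_all <- function(z, y, t, bw = NULL, n_eval = 20) {
  z <- as_obs_matrix(z, "z")
  bw <- bw %||% stats::bw.nrd0(t)
  if (!is.finite(bw) || bw <= 0) bw <- max(sd(t), 1e-8)
  ev <- cdcor_eval_points(t, n_eval)
  W <- cdcor_kernel_weights(t, ev, bw)
  cpp_cdcor_multi(z, y, W)
}
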