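# Outcome-model-free adaptive-lasso selection for the treatment (GPS)
# model.  The penalty weight for covariate j is built from its conditional
# distance correlation with the outcome given the treatment, so covariates
# that only predict the treatment (instrumental variables) are penalized
# heavily while confounders and prognostic covariates are kept cheap.

default_lambda_exponents <- function() {
  c(-10, -5, -2, -1.25, -1, -0.75, -0.5, -0.25, 0.25, 0.49)
}

#' Coupled adaptive-lasso exponent for a penalty level
#'
#' For a penalty \eqn{\lambda_n = n^a}, the selection-consistency coupling
#' \eqn{\lambda_n n^{\gamma/2 - 1} = n^2} pins down the penalty-weight
#' exponent: \eqn{\gamma = 2(3 - a)}.  Values of `a` at or above 2.5 would
#' give \eqn{\gamma \le 1}, violating the adaptive-lasso condition, and
#' are rejected.
#'
#' @param exponent grid exponent a, so that \eqn{\lambda_n = n^a}.
#' @return gamma (> 1).
#' @export
gamma_for_lambda <- function(exponent) {
  check_numeric(exponent, "exponent")
  g <- 2 * (3 - exponent)
  if (any(g <= 1))
    stop("exponent ", paste(exponent[g <= 1], collapse = ", "),
         " gives gamma <= 1, violating the tuning-parameter condition")
  g
}

#' Penalty (lambda) grid
#'
#' The default search grid \eqn{\lambda_n = n^a} over exponents
#' \{-10, -5, -2, -1.25, -1, -0.75, -0.5, -0.25, 0.25, 0.49\}, with the
#' coupled gamma for each.
#'
#' @param n sample size.
#' @param exponents grid exponents.
#' @return data.frame with columns `exponent`, `lambda`, `gamma`.
#' @export
lambda_grid <- function(n, exponents = default_lambda_exponents()) {
  if (n < 2) stop("n must be >= 2")
  data.frame(exponent = exponents,
             lambda = n^exponents,
             gamma = gamma_for_lambda(exponents))
}

#' Outcome-relevance penalty weights
#'
#' Computes \eqn{d_j = |cdcor(Z_j, Y | T)|} for every covariate and turns
#' them into adaptive-lasso penalty weights
#' \eqn{\hat w_j = (d_j / \max_k d_k)^{-\gamma}} (the default
#' `direction = "inverse"`: covariates weakly related to the outcome are
#' penalized heavily).  `direction = "literal"` uses the non-inverted
#' exponent \eqn{(d_j/\max_k d_k)^{\gamma}} instead.  Covariates with
#' \eqn{d_j = 0} get an infinite weight (deterministic exclusion); ties in
#' the maximum are broken by first index.
#'
#' @param z covariate matrix (n x p).
#' @param y outcome vector.
#' @param t treatment vector.
#' @param gamma penalty-weight exponent (> 1).
#' @param direction `"inverse"` (default) or `"literal"`.
#' @param dcor_raw optional precomputed vector of conditional distance
#'   correlations (skips the kernel computation).
#' @param bw,n_eval passed to [cdcor()].
#' @return An object of class `"penalty_weights"`: list with `w_hat`,
#'   `dcor_raw`, `gamma`, `direction`.
#' @export
penalty_weights <- function(z, y, t, gamma, direction = c("inverse",
                            "literal"), dcor_raw = NULL, bw = NULL,
                            n_eval = 20) {
  direction <- match.arg(direction)
  z <- as_obs_matrix(z, "z")
  if (gamma <= 1) stop("gamma must be > 1")
  if (is.null(dcor_raw)) {
    if (nrow(z) < 10L) stop("invalid sample: need n >= 10")
    dcor_raw <- abs(cdcor_all(z, y, t, bw = bw, n_eval = n_eval))
  }
  if (length(dcor_raw) != ncol(z)) stop("dcor_raw has wrong length")
  dmax <- max(dcor_raw)
  if (dmax <= 0) stop("no covariate related to outcome")
  ratio <- dcor_raw / dmax
  w_hat <- if (direction == "inverse") {
    ifelse(dcor_raw == 0, Inf, ratio^(-gamma))
  } else ratio^gamma
  structure(list(w_hat = w_hat, dcor_raw = dcor_raw, gamma = gamma,
                 direction = direction),
            class = "penalty_weights")
}

#' Weighted lasso for the treatment model
#'
#' Solves \eqn{\min_\alpha \|T - \alpha_0 - Z\alpha\|_2^2 +
#' \lambda_n \sum_j \hat w_j |\alpha_j|}.  Covariates are standardized
#' (and the treatment centered) before fitting so penalty weights are
#' comparable across covariates; coefficients are reported on the original
#' scale.  Solved by deterministic cyclic coordinate descent with
#' per-coordinate penalties, which is equivalent to the usual
#' reparameterization \eqn{\tilde Z_j = Z_j / \hat w_j} followed by a
#' plain lasso.  Covariates with infinite weight are dropped before
#' fitting and reported with a zero coefficient.
#'
#' @param z covariate matrix (n x p).
#' @param t treatment vector.
#' @param penalty a `"penalty_weights"` object, or a bare numeric vector
#'   of weights.
#' @param lambda penalty level \eqn{\lambda_n \ge 0}.
#' @param tol,maxit coordinate-descent tolerance and pass cap.
#' @param init optional warm-start coefficients (standardized scale).
#' @return list with `coef` (length p, original scale), `intercept`,
#'   `active` (indices of nonzero coefficients), and `coef_std`
#'   (standardized scale, for warm starts and KKT checks).
#' @export
weighted_lasso <- function(z, t, penalty, lambda, tol = 1e-7,
                           maxit = 1e5, init = NULL) {
  z <- as_obs_matrix(z, "z")
  check_numeric(t, "t")
  if (lambda < 0) stop("lambda must be >= 0")
  n <- nrow(z); p <- ncol(z)
  if (length(t) != n) stop("t and z sizes differ")
  w_hat <- if (inherits(penalty, "penalty_weights")) penalty$w_hat
           else penalty
  if (length(w_hat) != p) stop("penalty weights have wrong length")
  if (any(w_hat < 0)) stop("penalty weights must be nonnegative")
  mz <- colMeans(z)
  sz <- apply(z, 2, sd)
  usable <- which(is.finite(w_hat) & sz > 0)
  coef_full <- numeric(p)
  names(coef_full) <- colnames(z)
  mt <- mean(t)
  if (length(usable) == 0L)
    return(list(coef = coef_full, intercept = mt, active = integer(0),
                coef_std = numeric(0), usable = integer(0)))
  zs <- scale(z[, usable, drop = FALSE], center = mz[usable],
              scale = sz[usable])
  lam <- lambda * w_hat[usable]
  # infinite-weight covariates already excluded; cap absurdly large finite
  # penalties to keep the arithmetic stable (they are inactive anyway)
  lam <- pmin(lam, 1e300)
  b0 <- init
  if (is.null(b0) || length(b0) != length(usable))
    b0 <- numeric(length(usable))
  bs <- cpp_cd_lasso(zs, t - mt, lam, b0, tol, as.integer(maxit))
  coef_full[usable] <- bs / sz[usable]
  active <- which(coef_full != 0)
  list(coef = coef_full,
       intercept = mt - sum(coef_full * mz),
       active = active,
       coef_std = bs,
       usable = usable)
}

#' Selection path over the penalty grid
#'
#' For each \eqn{\lambda_n = n^a} on the grid: the coupled gamma is
#' computed, penalty weights are rebuilt from the (cached) conditional
#' distance correlations with that gamma, and the weighted lasso is fit.
#' Conditional distance correlations are computed once; only the exponent
#' changes along the path.
#'
#' @param t treatment vector.
#' @param y outcome vector.
#' @param z covariate matrix (n x p).
#' @param exponents grid exponents (default [default_lambda_exponents()]).
#' @param direction,bw,n_eval passed to [penalty_weights()].
#' @param dcor_raw optional precomputed conditional distance correlations
#'   (length p), bypassing the kernel computation.
#' @param tol,maxit passed to [weighted_lasso()].
#' @return An object of class `"goaldr_path"`: list with `records` (one
#'   per lambda: exponent, lambda, gamma, coef, intercept, active),
#'   `dcor_raw`, `summary` (data.frame of exponent, lambda, gamma,
#'   active-set size).
#' @export
selection_path <- function(t, y, z, exponents = default_lambda_exponents(),
                           direction = "inverse", bw = NULL, n_eval = 20,
                           tol = 1e-7, maxit = 1e5, dcor_raw = NULL) {
  z <- as_obs_matrix(z, "z")
  n <- nrow(z)
  grid <- lambda_grid(n, exponents)
  if (is.null(dcor_raw))
    dcor_raw <- abs(cdcor_all(z, y, t, bw = bw, n_eval = n_eval))
  if (max(dcor_raw) <= 0) stop("no covariate related to outcome")
  ord <- order(grid$lambda, decreasing = TRUE)   # sparse -> dense warm start
  records <- vector("list", nrow(grid))
  warm <- NULL
  for (i in ord) {
    pw <- penalty_weights(z, y, t, gamma = grid$gamma[i],
                          direction = direction, dcor_raw = dcor_raw)
    fit <- weighted_lasso(z, t, pw, grid$lambda[i], tol = tol,
                          maxit = maxit, init = warm)
    warm <- fit$coef_std
    records[[i]] <- list(exponent = grid$exponent[i],
                         lambda = grid$lambda[i],
                         gamma = grid$gamma[i],
                         coef = fit$coef,
                         intercept = fit$intercept,
                         active = fit$active)
  }
  sizes <- vapply(records, function(r) length(r$active), integer(1))
  if (any(diff(sizes[order(grid$lambda)]) > 0))
    warning("active-set size not monotone along the lambda path")
  structure(list(records = records, dcor_raw = dcor_raw, n = n,
                 summary = cbind(grid, size = sizes)),
            class = "goaldr_path")
}

#' @method print goaldr_path
#' @export
print.goaldr_path <- function(x, ...) {
  cat("Adaptive-lasso selection path (", nrow(x$summary),
      " penalty values, n = ", x$n, ")\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
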