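# Dual-weight distance correlation: the tuning criterion that picks the
# lasso penalty.  Each covariate's residual (weighted) imbalance with the
# treatment is weighted by the square of its conditional distance
# correlation with the outcome, so imbalance in confounders and prognostic
# covariates dominates the criterion while instrumental and spurious
# covariates barely register.

#' Dual-weight distance correlation criterion
#'
#' \deqn{DWDC = \sum_{j=1}^{p} |cdcor(Z_j, Y|T)|^2 \,
#'   |dcor_w(Z_j, T)|}
#' summed over all p covariates (the balance weights depend on the
#' selected subset; the summand does not).
#'
#' @param z covariate matrix (n x p).
#' @param t treatment vector.
#' @param w balance weight vector.
#' @param dcor_raw length-p vector of conditional distance correlations
#'   \eqn{|cdcor(Z_j, Y|T)|}; computed from `y` if omitted.
#' @param y outcome vector (only needed when `dcor_raw` is missing).
#' @param bw,n_eval passed to the conditional dcor when it is computed.
#' @return Nonnegative scalar.
#' @export
dwdc <- function(z, t, w, dcor_raw = NULL, y = NULL, bw = NULL,
                 n_eval = 20) {
  z <- as_obs_matrix(z, "z")
  check_numeric(t, "t")
  check_weights(w, nrow(z))
  if (is.null(dcor_raw)) {
    if (is.null(y)) stop("supply either dcor_raw or y")
    dcor_raw <- abs(cdcor_all(z, y, t, bw = bw, n_eval = n_eval))
  }
  if (length(dcor_raw) != ncol(z)) stop("dcor_raw has wrong length")
  bal <- drop(cpp_wdcor_multi(z, t, cbind(w)))
  sum(dcor_raw^2 * abs(bal))
}

#' Select the penalty by minimizing DWDC
#'
#' For every record on a selection path, balance weights are solved on
#' that record's active set (uniform weights for an empty set; solutions
#' are cached per unique active set) and the DWDC criterion is evaluated;
#' the record with minimal DWDC wins, ties broken toward the larger
#' penalty (sparser model).
#'
#' @param path a `"goaldr_path"` from [selection_path()].
#' @param z covariate matrix used to build the path.
#' @param t treatment vector.
#' @param ridge,floor passed to [dcow_weights()].
#' @return list with `best` (the winning record, augmented with `w`,
#'   `dwdc`) and `trace` (data.frame: exponent, lambda, gamma, size,
#'   dwdc).
#' @export
select_lambda <- function(path, z, t, ridge = 0.1, floor = 0) {
  if (!inherits(path, "goaldr_path")) stop("'path' must be a goaldr_path")
  z <- as_obs_matrix(z, "z")
  n <- nrow(z)
  records <- path$records
  if (length(records) == 0L) stop("empty selection path")
  keys <- vapply(records, function(r) paste(r$active, collapse = ","),
                 character(1))
  uk <- unique(keys)
  first <- match(uk, keys)
  Wm <- matrix(NA_real_, n, length(uk))
  for (u in seq_along(uk)) {
    act <- records[[first[u]]]$active
    Wm[, u] <- if (length(act) == 0L) rep(1, n) else
      dcow_weights(t, z[, act, drop = FALSE], ridge = ridge,
                   floor = floor)$w
  }
  # one batched balance sweep over all unique weight vectors
  bal <- cpp_wdcor_multi(z, t, Wm)
  dw_u <- colSums(path$dcor_raw^2 * abs(bal))
  ku <- match(keys, uk)
  vals <- dw_u[ku]
  lambdas <- vapply(records, `[[`, numeric(1), "lambda")
  near <- which(vals <= min(vals) + 1e-12)
  best_i <- near[which.max(lambdas[near])]
  best <- records[[best_i]]
  best$w <- Wm[, ku[best_i]]
  best$dwdc <- vals[best_i]
  trace <- data.frame(
    exponent = vapply(records, `[[`, numeric(1), "exponent"),
    lambda = lambdas,
    gamma = vapply(records, `[[`, numeric(1), "gamma"),
    size = vapply(records, function(r) length(r$active), integer(1)),
    dwdc = vals)
  list(best = best, trace = trace)
}
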