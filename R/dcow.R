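# Distance-covariance optimal weights (DCOWs): subject weights that
# decorrelate the treatment from a covariate subset, solved as a convex
# quadratic program.

# Primal active-set solver for
#   min  1/2 w'H w + c'w   s.t.  E w = d,  w >= lo
# H must be positive definite.  Bounds are handled by clamping: violated
# bounds are added (batch) as equalities, bound multipliers are checked at
# candidate solutions and the most negative one released.
qp_active_set <- function(H, cvec, E, d, lo, maxit = 200L) {
  n <- ncol(H)
  # drop linearly dependent equality rows
  qe <- qr(t(E))
  if (qe$rank < nrow(E)) {
    keep <- qe$pivot[seq_len(qe$rank)]
    E <- E[keep, , drop = FALSE]
    d <- d[keep]
  }
  m <- nrow(E)
  clamped <- logical(n)
  for (it in seq_len(maxit)) {
    free <- which(!clamped)
    nf <- length(free)
    if (nf < m) return(list(status = "infeasible-active-set"))
    Ef <- E[, free, drop = FALSE]
    Hff <- H[free, free, drop = FALSE]
    rhs1 <- -cvec[free]
    rhs2 <- d
    if (any(clamped)) {
      wc <- lo[clamped]
      rhs1 <- rhs1 - H[free, clamped, drop = FALSE] %*% wc
      rhs2 <- rhs2 - E[, clamped, drop = FALSE] %*% wc
    }
    K <- rbind(cbind(Hff, t(Ef)),
               cbind(Ef, matrix(0, m, m)))
    sol <- tryCatch(solve(K, c(rhs1, rhs2)), error = function(e) NULL)
    if (is.null(sol)) return(list(status = "singular-kkt"))
    w <- lo
    w[free] <- sol[seq_len(nf)]
    nu <- sol[nf + seq_len(m)]
    viol <- !clamped & (w < lo - 1e-9)
    if (any(viol)) {
      clamped <- clamped | viol
      next
    }
    if (any(clamped)) {
      g <- drop(H %*% w + cvec + t(E) %*% nu)
      mu <- g[clamped]
      if (any(mu < -1e-8)) {
        idx <- which(clamped)
        clamped[idx[which.min(mu)]] <- FALSE
        next
      }
    }
    return(list(status = "ok", w = w, nu = nu, iterations = it))
  }
  list(status = "maxit")
}

#' Distance-covariance optimal balance weights
#'
#' Solves for nonnegative subject weights, summing to n, that minimize the
#' weighted squared distance covariance between the treatment and the
#' selected covariate block, plus a ridge dispersion penalty keeping the
#' weights near uniform:
#' \deqn{\min_w \; wdcov^2_w(T, Z_{sub}) + \frac{ridge}{n}\sum_i (w_i-1)^2}
#' subject to \eqn{\sum_i w_i = n}, \eqn{w_i \ge} `floor`, and
#' preservation of the (first-moment) marginals: the weighted means of the
#' treatment and of each selected covariate equal their sample means.
#' The objective is a convex quadratic in w, solved by a primal
#' active-set method.  With an empty covariate block the uniform weights
#' are returned without solving.
#'
#' @param t treatment vector (length n).
#' @param z_sub matrix of currently selected covariates (n x q, q >= 0);
#'   `NULL` or zero columns yields uniform weights.
#' @param ridge nonnegative dispersion penalty (default 0.1; larger
#'   values keep weights closer to uniform at the cost of residual
#'   imbalance).
#' @param floor lower bound on individual weights (default 0).
#' @param maxit active-set iteration cap.
#' @return An object of class `"dcow"`: list with `w` (the weights),
#'   `objective`, `objective_uniform`, `status`, `active_bounds`.
#' @export
dcow_weights <- function(t, z_sub = NULL, ridge = 0.1, floor = 0,
                         maxit = 200L) {
  check_numeric(t, "t")
  n <- length(t)
  if (n < 10L) stop("invalid sample: DCOW needs n >= 10")
  if (ridge < 0) stop("'ridge' must be nonnegative")
  if (floor < 0 || floor >= 1) stop("'floor' must be in [0, 1)")
  if (!is.null(z_sub)) z_sub <- as_obs_matrix(z_sub, "z_sub")
  q <- if (is.null(z_sub)) 0L else ncol(z_sub)
  if (q > 0L && nrow(z_sub) != n) stop("t and z_sub sizes differ")
  out <- list(n = n, q = q, ridge = ridge, floor = floor)
  if (q == 0L) {
    out <- c(out, list(w = rep(1, n), status = "uniform",
                       objective = 0, objective_uniform = 0,
                       active_bounds = 0L))
    class(out) <- "dcow"
    return(out)
  }
  A <- cpp_dcenter(cpp_dist_mat(z_sub))
  B <- cpp_dcenter(cpp_dist_vec(t))
  Q <- A * B                       # PSD (Schur product of two NSD negatives)
  Q <- (Q + t(Q)) / 2
  n2 <- n * n
  H <- 2 * Q / n2 + diag(2 * ridge / n, n)
  cvec <- rep(-2 * ridge / n, n)
  E <- rbind(rep(1, n), t, t(z_sub))
  d <- c(n, sum(t), colSums(z_sub))
  sol <- qp_active_set(H, cvec, E, d, rep(floor, n), maxit = maxit)
  if (sol$status != "ok")
    stop("DCOW solver failed (status: ", sol$status, ")")
  w <- pmax(sol$w, floor)
  w <- w * (n / sum(w))            # renormalize away last-digit drift
  obj <- function(w) drop(w %*% Q %*% w) / n2 + ridge / n * sum((w - 1)^2)
  out <- c(out, list(w = w, status = "ok",
                     objective = obj(w),
                     objective_uniform = obj(rep(1, n)),
                     active_bounds = sum(abs(w - floor) < 1e-8),
                     iterations = sol$iterations))
  class(out) <- "dcow"
  out
}

#' @method print dcow
#' @export
print.dcow <- function(x, ...) {
  cat("DCOW balance weights: n =", x$n, ", q =", x$q,
      ", status:", x$status, "\n")
  cat(sprintf("  objective %.6g (uniform %.6g), weights in [%.3f, %.3f]\n",
              x$objective, x$objective_uniform, min(x$w), max(x$w)))
  invisible(x)
}

#' Per-covariate balance diagnostics
#'
#' Weighted and unweighted distance correlation of each covariate with the
#' treatment, one row per covariate.
#'
#' @param t treatment vector.
#' @param z covariate matrix (n x p).
#' @param w weight vector (e.g. from [dcow_weights()]).
#' @return A data.frame with columns `covariate`, `unweighted`, `weighted`.
#' @export
balance_table <- function(t, z, w) {
  z <- as_obs_matrix(z, "z")
  check_numeric(t, "t")
  check_weights(w, nrow(z))
  b <- cpp_wdcor_multi(z, t, cbind(rep(1, nrow(z)), w))
  un <- b[, 1]
  wt <- b[, 2]
  data.frame(covariate = colnames(z) %||% paste0("Z", seq_len(ncol(z))),
             unweighted = un, weighted = wt)
}
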