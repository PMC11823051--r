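# Pseudo-outcome doubly robust estimation of the dose-response function.
# The pseudo-outcome for subject i is
#   theta_i = (1/n) sum_k mu(Z_k, T_i)  +  (Y_i - mu(Z_i, T_i)) w_i
# i.e. a marginalized-prediction term plus a balance-weighted residual;
# regressing theta on T estimates E[Y(t)].  The estimate is consistent if
# either the weights (GPS side) or mu (outcome side) is right.

#' Doubly robust pseudo-outcome
#'
#' @param fit an `"outcome_ensemble"` for \eqn{\hat\mu(Z, T)}, or a
#'   vectorized function `mu(z, t)` taking a covariate matrix and a
#'   treatment vector of matching length (useful for plugging in a known
#'   outcome model).
#' @param t treatment vector.
#' @param y outcome vector.
#' @param z_active covariate matrix the ensemble was fit on (or `NULL`).
#' @param w balance weight vector.
#' @return Object of class `"pseudo_outcome"`: `theta`, and its two
#'   components `term1` (marginalized prediction) and `term2` (weighted
#'   residual), with `theta == term1 + term2` elementwise.
#' @export
build_pseudo_outcome <- function(fit, t, y, z_active, w) {
  if (!inherits(fit, "outcome_ensemble") && !is.function(fit))
    stop("'fit' must be an outcome ensemble or a function mu(z, t)")
  n <- length(t)
  if (length(y) != n) stop("t and y sizes differ")
  check_weights(w, n)
  has_z <- if (is.function(fit)) !is.null(z_active) && NCOL(z_active) > 0
           else fit$q > 0L
  if (has_z) {
    z_active <- as_obs_matrix(z_active, "z_active")
    if (nrow(z_active) != n) stop("z_active has wrong number of rows")
    # M[k, i] = mu(Z_k, T_i)
    M <- if (is.function(fit)) {
      vapply(t, function(ti) fit(z_active, rep(ti, n)), numeric(n))
    } else predict(fit, z_active, t, cross = TRUE)
    term1 <- colMeans(M)
    mu_own <- M[cbind(seq_len(n), seq_len(n))]
  } else {
    mu_own <- if (is.function(fit)) fit(NULL, t) else predict(fit, NULL, t)
    term1 <- mu_own                      # no covariates: nothing to average
  }
  term2 <- (y - mu_own) * w
  structure(list(theta = term1 + term2, term1 = term1, term2 = term2),
            class = "pseudo_outcome")
}

#' Regress the pseudo-outcome on the treatment
#'
#' Ordinary least squares of the pseudo-outcome on a polynomial basis of
#' the treatment (default linear), returning the slope with its
#' conventional standard error and normal-approximation 95% CI.
#'
#' @param theta a `"pseudo_outcome"` or numeric vector.
#' @param t treatment vector.
#' @param degree polynomial degree (1 = linear).
#' @param ci_level confidence level.
#' @return list with `slope`, `intercept`, `analytic_sd`, `ci`, `fitted`,
#'   `coefficients`, and the underlying `lm` fit.
#' @export
regress_drf <- function(theta, t, degree = 1L, ci_level = 0.95) {
  if (inherits(theta, "pseudo_outcome")) theta <- theta$theta
  check_numeric(theta, "theta"); check_numeric(t, "t")
  if (length(theta) != length(t)) stop("theta and t sizes differ")
  if (length(t) < 3L) stop("need n >= 3")
  if (sd(t) == 0) stop("treatment is constant")
  df <- data.frame(theta = theta, t = t)
  fit <- if (degree == 1L) lm(theta ~ t, data = df)
         else lm(theta ~ poly(t, degree, raw = TRUE), data = df)
  sm <- summary(fit)$coefficients
  slope <- unname(sm[2, 1]); se <- unname(sm[2, 2])
  zq <- qnorm(1 - (1 - ci_level) / 2)
  list(slope = slope, intercept = unname(sm[1, 1]), analytic_sd = se,
       ci = c(lower = slope - zq * se, upper = slope + zq * se),
       ci_level = ci_level, fitted = unname(fitted(fit)),
       coefficients = coef(fit), lm = fit)
}

validate_trisample <- function(t, y, z) {
  check_numeric(t, "t"); check_numeric(y, "y")
  if (is.null(z) || NCOL(z) == 0L) stop("no covariates supplied")
  z <- as_obs_matrix(z, "z")
  n <- length(t)
  if (length(y) != n || nrow(z) != n)
    stop("t, y, z must have matching sample sizes")
  if (is.null(colnames(z))) colnames(z) <- paste0("Z", seq_len(ncol(z)))
  z
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Doubly robust dose-response estimation with covariate selection
#'
#' The full pipeline: conditional-distance-correlation penalty weights and
#' adaptive-lasso selection path over the penalty grid; DWDC tuning of the
#' penalty; distance-covariance optimal balance weights on the selected
#' covariates; a stacked outcome ensemble on the selected covariates; the
#' doubly robust pseudo-outcome; and a linear (by default) dose-response
#' regression.
#'
#' @param t continuous treatment vector (length n >= 30).
#' @param y outcome vector.
#' @param z covariate matrix or data.frame (n x p, p >= 1).
#' @param control a [goaldr_control()] list.
#' @param boot if `TRUE`, attach bootstrap SE / CI via [drf_boot()].
#' @return Object of class `"drf_fit"` with components `slope`,
#'   `intercept`, `analytic_sd`, `ci`, `selected` (column indices),
#'   `weights`, `dwdc_trace`, `path_summary`, `pseudo`, plus the inputs
#'   needed to refit (`t`, `y`, `z`, `control`, `method`).
#' @seealso [sldr()] for the density-ratio comparator, [drf_boot()] for
#'   bootstrap uncertainty.
#' @examples
#' \donttest{
#' d <- sim_drf_data("SoSt", n = 120, p = 10, seed = 1)
#' fit <- goaldr(d$t, d$y, d$z, control = goaldr_control(fast = TRUE))
#' summary(fit)
#' }
#' @export
goaldr <- function(t, y, z, control = goaldr_control(), boot = FALSE) {
  control <- as_goaldr_control(control)
  z <- validate_trisample(t, y, z)
  if (length(t) < 30L) stop("need n >= 30")
  path <- run_stage("selection", selection_path(
    t, y, z, exponents = control$lambda_exponents,
    direction = control$penalty_direction, bw = control$cdcor_bw,
    n_eval = control$cdcor_n_eval))
  sel <- run_stage("dwdc-tuning", select_lambda(
    path, z, t, ridge = control$ridge, floor = control$weight_floor))
  active <- sel$best$active
  w <- sel$best$w
  ens <- run_stage("outcome-model", fit_outcome_ensemble(
    if (length(active)) z[, active, drop = FALSE] else NULL, t, y,
    control))
  pseudo <- run_stage("pseudo-outcome", build_pseudo_outcome(
    ens, t, y, if (length(active)) z[, active, drop = FALSE] else NULL,
    w))
  reg <- run_stage("drf-regression", regress_drf(
    pseudo, t, degree = control$drf_degree))
  out <- structure(list(
    method = "GOALDeR", slope = reg$slope, intercept = reg$intercept,
    analytic_sd = reg$analytic_sd, ci = reg$ci, ci_level = reg$ci_level,
    coefficients = reg$coefficients,
    selected = active, selected_names = colnames(z)[active],
    weights = w, dwdc_trace = sel$trace, path_summary = path$summary,
    dcor_raw = path$dcor_raw, pseudo = pseudo, ensemble = ens,
    t = t, y = y, z = z, control = control, call = match.call()),
    class = "drf_fit")
  if (boot) {
    bt <- drf_boot(out, B = control$boot_B, seed = control$seed)
    out$boot_sd <- bt$boot_sd
    out$boot_ci <- bt$percentile_ci
  }
  out
}

#' SL-DR comparator: density-ratio weights on all covariates
#'
#' Doubly robust pseudo-outcome estimator that skips covariate selection
#' and balance optimization: weights are the normal-approximation density
#' ratio \eqn{f_T(T_i) / f_{T|Z}(T_i|Z_i)} with the conditional mean of
#' the treatment fit by the stacked ensemble on all covariates, and the
#' outcome model is the stacked ensemble on all covariates.
#'
#' @inheritParams goaldr
#' @return Object of class `"drf_fit"` (method tag `"SL-DR"`).
#' @export
sldr <- function(t, y, z, control = goaldr_control(), boot = FALSE) {
  control <- as_goaldr_control(control)
  z <- validate_trisample(t, y, z)
  if (length(t) < 30L) stop("need n >= 30")
  gps <- run_stage("gps-model", fit_gps_normal(z, t, control))
  w <- run_stage("gps-weights", gps_ratio_weights(gps, t))
  ens <- run_stage("outcome-model", fit_outcome_ensemble(z, t, y, control))
  pseudo <- run_stage("pseudo-outcome",
                      build_pseudo_outcome(ens, t, y, z, w))
  reg <- run_stage("drf-regression",
                   regress_drf(pseudo, t, degree = control$drf_degree))
  out <- structure(list(
    method = "SL-DR", slope = reg$slope, intercept = reg$intercept,
    analytic_sd = reg$analytic_sd, ci = reg$ci, ci_level = reg$ci_level,
    coefficients = reg$coefficients, selected = seq_len(ncol(z)),
    selected_names = colnames(z), weights = w, gps = gps,
    pseudo = pseudo, ensemble = ens,
    t = t, y = y, z = z, control = control, call = match.call()),
    class = "drf_fit")
  if (boot) {
    bt <- drf_boot(out, B = control$boot_B, seed = control$seed)
    out$boot_sd <- bt$boot_sd
    out$boot_ci <- bt$percentile_ci
  }
  out
}

#' Selection-only run
#'
#' Runs the covariate-selection half of the pipeline (penalty path + DWDC
#' tuning + balance weights) without fitting the outcome model; useful for
#' studying which covariates would be balanced.
#'
#' @inheritParams goaldr
#' @return list with `selected`, `weights`, `dwdc_trace`, `path_summary`,
#'   `dcor_raw`.
#' @export
goaldr_select <- function(t, y, z, control = goaldr_control()) {
  control <- as_goaldr_control(control)
  z <- validate_trisample(t, y, z)
  path <- selection_path(t, y, z, exponents = control$lambda_exponents,
                         direction = control$penalty_direction,
                         bw = control$cdcor_bw,
                         n_eval = control$cdcor_n_eval)
  sel <- select_lambda(path, z, t, ridge = control$ridge,
                       floor = control$weight_floor)
  list(selected = sel$best$active,
       selected_names = colnames(z)[sel$best$active],
       weights = sel$best$w, dwdc_trace = sel$trace,
       path_summary = path$summary, dcor_raw = path$dcor_raw)
}

#' Bootstrap standard error for a fitted dose-response model
#'
#' Nonparametric bootstrap: subjects are resampled with replacement and
#' the entire pipeline (selection, tuning, weighting, outcome fit) is
#' re-run on each replicate.  Replicates that fail are skipped with a
#' warning; more than 10% failures is an error.
#'
#' @param object a `"drf_fit"` from [goaldr()] or [sldr()].
#' @param B number of bootstrap replicates (>= 50 recommended; >= 2
#'   required).
#' @param seed RNG seed for the resampling.
#' @return list with `boot_sd`, `percentile_ci`, `normal_ci`, `slopes`.
#' @export
drf_boot <- function(object, B = 100L, seed = NULL) {
  if (!inherits(object, "drf_fit")) stop("'object' must be a drf_fit")
  if (B < 2L) stop("B must be >= 2")
  n <- length(object$t)
  refit <- if (object$method == "GOALDeR") goaldr else sldr
  idx <- with_seed(seed %||% object$control$seed,
                   replicate(B, sample.int(n, n, replace = TRUE),
                             simplify = FALSE))
  slopes <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    i <- idx[[b]]
    slopes[b] <- tryCatch(
      refit(object$t[i], object$y[i], object$z[i, , drop = FALSE],
            control = object$control)$slope,
      error = function(e) NA_real_)
  }
  fail <- sum(is.na(slopes))
  if (fail > 0)
    warning(fail, " of ", B, " bootstrap replicates failed")
  if (fail > 0.1 * B)
    stop("more than 10% of bootstrap replicates failed")
  ok <- slopes[!is.na(slopes)]
  a <- (1 - object$ci_level) / 2
  zq <- qnorm(1 - a)
  list(boot_sd = sd(ok),
       percentile_ci = unname(quantile(ok, c(a, 1 - a))),
       normal_ci = c(object$slope - zq * sd(ok),
                     object$slope + zq * sd(ok)),
       slopes = slopes)
}

#' @method print drf_fit
#' @export
print.drf_fit <- function(x, ...) {
  cat(x$method, "dose-response fit\n")
  cat(sprintf("  slope %.4f (SE %.4f), 95%% CI [%.4f, %.4f]\n",
              x$slope, x$analytic_sd, x$ci[1], x$ci[2]))
  if (!is.null(x$boot_sd))
    cat(sprintf("  bootstrap SE %.4f, percentile CI [%.4f, %.4f]\n",
                x$boot_sd, x$boot_ci[1], x$boot_ci[2]))
  if (x$method == "GOALDeR")
    cat("  selected covariates:",
        if (length(x$selected)) paste(x$selected_names, collapse = ", ")
        else "(none)", "\n")
  invisible(x)
}

#' @method summary drf_fit
#' @export
summary.drf_fit <- function(object, ...) {
  structure(list(fit = object,
                 balance = balance_table(object$t, object$z,
                                         object$weights)),
            class = "summary.drf_fit")
}

#' @method print summary.drf_fit
#' @export
print.summary.drf_fit <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  cat(sprintf("  n = %d, p = %d, weights in [%.3f, %.3f]\n",
              length(f$t), ncol(f$z), min(f$weights), max(f$weights)))
  b <- x$balance
  sel <- if (length(f$selected)) f$selected else seq_len(nrow(b))
  cat("  balance on", if (length(f$selected)) "selected" else "all",
      "covariates (distance correlation with treatment):\n")
  print(b[sel, , drop = FALSE], row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.drf_fit <- function(object, ...) object$coefficients

#' @export
confint.drf_fit <- function(object, parm, level = 0.95, ...) {
  zq <- qnorm(1 - (1 - level) / 2)
  m <- cbind(object$slope - zq * object$analytic_sd,
             object$slope + zq * object$analytic_sd)
  dimnames(m) <- list("t", sprintf("%.1f %%", c((1 - level) / 2,
                                                1 - (1 - level) / 2) * 100))
  m
}

#' Predict the dose-response function at treatment values
#'
#' @param object a `"drf_fit"`.
#' @param t treatment values (defaults to the observed treatments).
#' @param ... unused.
#' @return Estimated E\[Y(t)\].
#' @export
predict.drf_fit <- function(object, t = object$t, ...) {
  degree <- length(object$coefficients) - 1L
  drop(outer(t, 0:degree, `^`) %*% object$coefficients)
}

#' @export
residuals.drf_fit <- function(object, ...) {
  object$pseudo$theta - predict(object)
}

#' Plot the estimated dose-response function
#'
#' Pseudo-outcome scatter with the fitted dose-response curve.
#'
#' @param x a `"drf_fit"`.
#' @param ... passed to [plot()].
#' @export
plot.drf_fit <- function(x, ...) {
  ord <- order(x$t)
  plot(x$t, x$pseudo$theta, xlab = "treatment", ylab = "pseudo-outcome",
       main = paste(x$method, "dose-response"), col = "grey40", ...)
  graphics::lines(x$t[ord], predict(x)[ord], col = "red3", lwd = 2)
  invisible(x)
}
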