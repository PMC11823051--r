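# Flexible outcome regression mu(Z, T): a stacked ensemble over the four
# learner families (penalized linear, gradient-boosted trees, random
# forest, support-vector regression), combined by nonnegative least
# squares on K-fold out-of-fold predictions.  Also the normal-density GPS
# used by the SL-DR comparator.

fit_one_learner <- function(name, X, y, control, seed) {
  X <- as.matrix(X)
  switch(name,
    lasso = {
      if (ncol(X) < 2L) {
        structure(list(fit = lm(y ~ X)), class = "goaldr_lm_learner")
      } else {
        fold <- with_seed(seed, sample(rep_len(seq_len(control$folds),
                                               nrow(X))))
        fit <- glmnet::cv.glmnet(X, y, foldid = fold, alpha = 1)
        structure(list(fit = fit), class = "goaldr_lasso_learner")
      }
    },
    xgb = {
      fit <- with_seed(seed, xgboost::xgb.train(
        params = list(objective = "reg:squarederror",
                      max_depth = control$xgb_depth, eta = control$xgb_eta,
                      nthread = 1),
        data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
        nrounds = control$xgb_nrounds, verbose = 0))
      structure(list(fit = fit), class = "goaldr_xgb_learner")
    },
    rf = {
      fit <- with_seed(seed, randomForest::randomForest(
        x = X, y = y, ntree = control$rf_trees))
      structure(list(fit = fit), class = "goaldr_rf_learner")
    },
    svm = {
      fit <- e1071::svm(x = X, y = y, kernel = "radial")
      structure(list(fit = fit), class = "goaldr_svm_learner")
    },
    stop("unknown learner: ", name))
}

predict_one_learner <- function(l, X) {
  X <- as.matrix(X)
  out <- switch(class(l)[1],
    goaldr_lm_learner = drop(cbind(1, X) %*% coef(l$fit)),
    goaldr_lasso_learner = drop(predict(l$fit, newx = X,
                                        s = "lambda.min")),
    goaldr_xgb_learner = predict(l$fit, xgboost::xgb.DMatrix(
      X, nthread = 1)),
    goaldr_rf_learner = drop(predict(l$fit, X)),
    goaldr_svm_learner = drop(predict(l$fit, X)),
    stop("unknown learner fit"))
  unname(out)
}

#' Stacked outcome-regression ensemble
#'
#' Fits \eqn{\hat\mu(Z, T)} as a convex (nonnegative, sum-one) stack of
#' the configured learners.  Stacking weights are solved by nonnegative
#' least squares of the outcome on K-fold out-of-fold predictions; the
#' constituent learners are then refit on the full data.  With `q = 0`
#' covariates the ensemble regresses on the treatment alone.
#'
#' @param z_active selected covariate matrix (n x q, q >= 0) or `NULL`.
#' @param t treatment vector.
#' @param y outcome vector.
#' @param control a [goaldr_control()] list.
#' @return Object of class `"outcome_ensemble"`: learner fits, stacking
#'   weights (`sum(weights) == 1`), fold count, out-of-fold predictions.
#' @export
fit_outcome_ensemble <- function(z_active, t, y, control = goaldr_control()) {
  control <- as_goaldr_control(control)
  check_numeric(t, "t"); check_numeric(y, "y")
  n <- length(y)
  if (!is.null(z_active) && ncol(as_obs_matrix(z_active)) == 0L)
    z_active <- NULL
  if (!is.null(z_active)) z_active <- as_obs_matrix(z_active, "z_active")
  if (n < 20L) stop("outcome ensemble needs n >= 20")
  if (n < 4L * control$folds)
    stop("n too small for ", control$folds, "-fold stacking")
  X <- cbind(z_active, t = t)
  out <- stack_ensemble(X, y, control, seed_offset = 0L)
  out$q <- ncol(X) - 1L
  out
}

# K-fold NNLS-stacked ensemble over an arbitrary feature matrix.
stack_ensemble <- function(X, y, control, seed_offset = 0L) {
  n <- nrow(X)
  seed <- (control$seed %||% 1L) + seed_offset
  folds <- with_seed(seed, sample(rep_len(seq_len(control$folds), n)))
  L <- length(control$learners)
  oof <- matrix(NA_real_, n, L, dimnames = list(NULL, control$learners))
  for (k in seq_len(control$folds)) {
    tr <- folds != k
    for (j in seq_len(L)) {
      l <- fit_one_learner(control$learners[j], X[tr, , drop = FALSE],
                           y[tr], control, seed + 100 * k + j)
      oof[!tr, j] <- predict_one_learner(l, X[!tr, , drop = FALSE])
    }
  }
  sw <- tryCatch(pracma::lsqnonneg(oof, y)$x, error = function(e) NULL)
  if (is.null(sw) || sum(sw) <= 0) sw <- rep(1 / L, L)
  sw <- sw / sum(sw)
  fits <- lapply(seq_len(L), function(j)
    fit_one_learner(control$learners[j], X, y, control, seed + j))
  structure(list(fits = fits, learners = control$learners, weights = sw,
                 folds = control$folds, oof = oof, q = ncol(X),
                 control = control),
            class = "outcome_ensemble")
}

#' Predict from the outcome ensemble
#'
#' @param object an `"outcome_ensemble"`.
#' @param z covariate rows (matrix with `object$q` columns, or `NULL`
#'   when the ensemble was fit without covariates).
#' @param t treatment value(s): a scalar (recycled over the rows of `z`)
#'   or a vector matching `nrow(z)`; with `cross = TRUE`, any vector.
#' @param cross if `TRUE`, return the full cross-prediction matrix with
#'   entry (i, j) = \eqn{\hat\mu(z_i, t_j)} (rows = covariate rows,
#'   columns = treatment values).
#' @param ... unused.
#' @return numeric vector, or an `nrow(z)` x `length(t)` matrix.
#' @export
predict.outcome_ensemble <- function(object, z = NULL, t, cross = FALSE,
                                     ...) {
  q <- object$q
  if (q > 0L) {
    z <- as_obs_matrix(z, "z")
    if (ncol(z) != q) stop("z must have ", q, " columns")
    nz <- nrow(z)
  } else {
    nz <- if (cross) 1L else length(t)
    z <- NULL
  }
  if (cross) {
    out <- matrix(NA_real_, nz, length(t))
    # chunk over treatment values to bound the design-matrix size
    chunk <- max(1L, floor(5e4 / max(nz, 1)))
    idx <- split(seq_along(t), ceiling(seq_along(t) / chunk))
    for (ii in idx) {
      Xb <- cbind(z[rep(seq_len(nz), times = length(ii)), , drop = FALSE],
                  t = rep(t[ii], each = nz))
      pb <- ensemble_predict_design(object, Xb)
      out[, ii] <- matrix(pb, nz, length(ii))
    }
    return(out)
  }
  if (length(t) == 1L) t <- rep(t, nz)
  if (q > 0L && length(t) != nz) stop("length(t) must match nrow(z)")
  X <- cbind(z, t = t)
  ensemble_predict_design(object, X)
}

ensemble_predict_design <- function(object, X) {
  preds <- vapply(object$fits, function(l) predict_one_learner(l, X),
                  numeric(nrow(X)))
  drop(preds %*% object$weights)
}

#' Normal-density generalized propensity score
#'
#' Normal approximation of the treatment's marginal and conditional
#' densities: the marginal is \eqn{N(\bar T, sd(T)^2)}; the conditional
#' mean \eqn{\hat m(Z)} is fit by the outcome ensemble on all supplied
#' covariates (`mean_model = "ensemble"`, the default) or by least
#' squares (`"linear"`), with residual standard deviation
#' \eqn{\hat\sigma}.  With no covariates the conditional equals the
#' marginal.
#'
#' @param z covariate matrix or `NULL`.
#' @param t treatment vector.
#' @param control a [goaldr_control()] list.
#' @param mean_model `"ensemble"` or `"linear"`.
#' @return Object of class `"gps_fit"`.
#' @export
fit_gps_normal <- function(z, t, control = goaldr_control(),
                           mean_model = c("ensemble", "linear")) {
  mean_model <- match.arg(mean_model)
  control <- as_goaldr_control(control)
  check_numeric(t, "t")
  n <- length(t)
  marg <- c(mean = mean(t), sd = sd(t))
  if (marg["sd"] <= 0) stop("treatment is constant")
  if (!is.null(z)) {
    z <- as_obs_matrix(z, "z")
    if (ncol(z) == 0L) z <- NULL
  }
  if (is.null(z)) {
    fit <- NULL; m_hat <- rep(marg[["mean"]], n); sigma <- marg[["sd"]]
  } else if (mean_model == "linear") {
    if (n <= ncol(z) + 1L) stop("need n > p for the linear mean model")
    df <- data.frame(z); df$.t <- t
    fit <- lm(.t ~ ., data = df)
    m_hat <- unname(fitted(fit)); sigma <- sd(residuals(fit))
  } else {
    # regress T on Z: reuse the ensemble machinery with Z as the features
    fit <- fit_ensemble_features(z, t, control)
    m_hat <- ensemble_predict_design(fit, as.matrix(z))
    sigma <- sd(t - m_hat)
  }
  if (!is.finite(sigma) || sigma <= 0)
    stop("degenerate conditional density: residual sd is zero")
  structure(list(marginal = marg, fit = fit, m_hat = m_hat, sigma = sigma,
                 mean_model = if (is.null(z)) "none" else mean_model),
            class = "gps_fit")
}

# Ensemble on an arbitrary feature matrix (no treatment column).
fit_ensemble_features <- function(X, y, control) {
  control <- as_goaldr_control(control)
  X <- as_obs_matrix(X, "X")
  stack_ensemble(X, y, control, seed_offset = 7L)
}

#' Density-ratio (inverse-GPS) balance weights
#'
#' \eqn{w_i = f_T(T_i) / f_{T|Z}(T_i | Z_i)} under the normal
#' approximations of [fit_gps_normal()], rescaled to sum to the sample
#' size.
#'
#' @param fit a `"gps_fit"`.
#' @param t treatment vector the fit was built on.
#' @return A weight vector (positive, summing to n).
#' @export
gps_ratio_weights <- function(fit, t) {
  if (!inherits(fit, "gps_fit")) stop("'fit' must be a gps_fit")
  num <- dnorm(t, fit$marginal[["mean"]], fit$marginal[["sd"]])
  den <- dnorm(t, fit$m_hat, fit$sigma)
  w <- num / pmax(den, 1e-300)
  w * (length(t) / sum(w))
}
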