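#' Control parameters for the dose-response pipeline
#'
#' Collects every tunable of the pipeline in one list.  `fast = TRUE`
#' switches the outcome ensemble to the two cheap learner families
#' (penalized linear + gradient boosting) and shortens the boosting run;
#' the default is the full four-family ensemble.
#'
#' @param learners character subset of `c("lasso", "xgb", "rf", "svm")`.
#' @param fast logical; use the reduced learner set.
#' @param folds stacking folds for the ensemble (default 5).
#' @param seed integer seed from which all learner/fold seeds derive.
#' @param lambda_exponents penalty-grid exponents.
#' @param penalty_direction `"inverse"` (default) or `"literal"`; see
#'   [penalty_weights()].
#' @param ridge DCOW dispersion penalty.
#' @param weight_floor DCOW lower bound on weights.
#' @param cdcor_n_eval evaluation points for the conditional dcor.
#' @param cdcor_bw kernel bandwidth (`NULL` = Silverman's rule).
#' @param drf_degree polynomial degree of the dose-response regression
#'   (default 1, linear).
#' @param boot_B bootstrap replicates for [drf_boot()].
#' @param xgb_nrounds,xgb_depth,xgb_eta gradient-boosting settings.
#' @param rf_trees random-forest trees.
#' @return A list of class `"goaldr_control"`.
#' @export
goaldr_control <- function(learners = c("lasso", "xgb", "rf", "svm"),
                           fast = FALSE,
                           folds = 5L,
                           seed = 1L,
                           lambda_exponents = default_lambda_exponents(),
                           penalty_direction = "inverse",
                           ridge = 0.1,
                           weight_floor = 0,
                           cdcor_n_eval = 20L,
                           cdcor_bw = NULL,
                           drf_degree = 1L,
                           boot_B = 100L,
                           xgb_nrounds = 150L,
                           xgb_depth = 3L,
                           xgb_eta = 0.1,
                           rf_trees = 300L) {
  learners <- match.arg(learners, c("lasso", "xgb", "rf", "svm"),
                        several.ok = TRUE)
  if (fast) {
    learners <- c("lasso", "xgb")
    xgb_nrounds <- min(xgb_nrounds, 80L)
  }
  if (folds < 2) stop("'folds' must be >= 2")
  if (drf_degree < 1) stop("'drf_degree' must be >= 1")
  structure(list(learners = learners, fast = fast, folds = as.integer(folds),
                 seed = seed, lambda_exponents = lambda_exponents,
                 penalty_direction = penalty_direction, ridge = ridge,
                 weight_floor = weight_floor,
                 cdcor_n_eval = as.integer(cdcor_n_eval),
                 cdcor_bw = cdcor_bw, drf_degree = as.integer(drf_degree),
                 boot_B = as.integer(boot_B),
                 xgb_nrounds = as.integer(xgb_nrounds),
                 xgb_depth = as.integer(xgb_depth), xgb_eta = xgb_eta,
                 rf_trees = as.integer(rf_trees)),
            class = "goaldr_control")
}

as_goaldr_control <- function(x) {
  if (inherits(x, "goaldr_control")) return(x)
  if (is.null(x)) return(goaldr_control())
  if (is.list(x)) return(do.call(goaldr_control, x))
  stop("'control' must be a goaldr_control() list")
}

#' Save / load a control list
#'
#' Round-trippable YAML serialization of a [goaldr_control()] object.
#'
#' @param control a `goaldr_control` object.
#' @param path file path.
#' @return `save_control` returns `path` invisibly; `load_control`
#'   returns the restored `goaldr_control`.
#' @export
save_control <- function(control, path) {
  control <- as_goaldr_control(control)
  x <- unclass(control)      # fast's reductions are idempotent, keep as-is
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname save_control
#' @export
load_control <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(goaldr_control, x)
}
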