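# Monte-Carlo study harness.  Covariates are equicorrelated standard
# Gaussians; the treatment is Gaussian around a setting-specific function
# m(Z) and the outcome Gaussian around eta*T + g(Z).  Six settings cover
# linear generating models at three confounding strengths (SoSt, SoWt,
# WoSt) and the misspecification grid (CoMt: nonlinear treatment model /
# linear outcome; MoCt: the reverse; MoMt: both nonlinear).

sim_settings <- function() c("SoSt", "SoWt", "WoSt", "CoMt", "MoCt", "MoMt")

# nonlinear block applied to Z1..Z4
nl_block <- function(z) {
  exp(z[, 1] / 2) +
    (z[, 2] / (1 + exp(z[, 1])) + 10) +
    (0.04 * z[, 1] * z[, 3] + 0.6)^3 +
    (z[, 2] + z[, 4])^2
}

sim_mean_funs <- function(setting) {
  switch(setting,
    SoSt = list(m = function(z) z[, 1] + z[, 2] + z[, 5] + z[, 6],
                g = function(z) z[, 1] + z[, 2] + z[, 3] + z[, 4]),
    SoWt = list(m = function(z) 0.5 * z[, 1] + 0.5 * z[, 2] + z[, 5] + z[, 6],
                g = function(z) z[, 1] + z[, 2] + z[, 3] + z[, 4]),
    WoSt = list(m = function(z) z[, 1] + z[, 2] + z[, 5] + z[, 6],
                g = function(z) 0.5 * z[, 1] + 0.5 * z[, 2] + z[, 3] + z[, 4]),
    CoMt = list(m = function(z) nl_block(z) + z[, 7] + z[, 8],
                g = function(z) rowSums(z[, 1:6, drop = FALSE])),
    MoCt = list(m = function(z) z[, 1] + z[, 2] + z[, 3] + z[, 4] +
                                z[, 7] + z[, 8],
                g = function(z) nl_block(z) + z[, 5] + z[, 6]),
    MoMt = list(m = function(z) nl_block(z) + z[, 7] + z[, 8],
                g = function(z) nl_block(z) + z[, 5] + z[, 6]),
    stop("unknown setting: ", setting))
}

# Covariate roles (confounders, prognostic, instrumental, spurious) per
# setting, used for grouped selection summaries.
sim_roles <- function(setting, p) {
  lin <- setting %in% c("SoSt", "SoWt", "WoSt")
  roles <- if (lin)
    list(confounder = 1:2, prognostic = 3:4, instrument = 5:6,
         spurious = if (p > 6) 7:p else integer(0))
  else
    list(confounder = 1:4, prognostic = 5:6, instrument = 7:8,
         spurious = if (p > 8) 9:p else integer(0))
  roles
}

#' Generate one simulated dataset
#'
#' Covariates \eqn{Z \sim N(0, \Sigma)} with unit variances and constant
#' pairwise correlation `rho` (one-factor construction); treatment
#' \eqn{T = m(Z) + N(0,1)}; outcome \eqn{Y = \eta T + g(Z) + N(0,1)},
#' with m and g given by `setting`.
#'
#' @param setting one of `"SoSt"`, `"SoWt"`, `"WoSt"` (linear scenario,
#'   confounders Z1-Z2, prognostic Z3-Z4, instruments Z5-Z6) or
#'   `"CoMt"`, `"MoCt"`, `"MoMt"` (misspecification scenario,
#'   confounders Z1-Z4, prognostic Z5-Z6, instruments Z7-Z8).
#' @param n sample size.
#' @param p covariate dimension (>= 6 linear settings, >= 8 otherwise).
#' @param rho equicorrelation in \[0, 1).
#' @param eta true linear dose-response slope.
#' @param seed RNG seed (restores the caller's RNG state).
#' @return Object of class `"trisample"`: list with `t`, `y`, `z`
#'   (colnames Z1..Zp), and the generating configuration.
#' @export
sim_drf_data <- function(setting = "SoSt", n = 200, p = 20, rho = 0,
                         eta = 2, seed = NULL) {
  setting <- match.arg(setting, sim_settings())
  pmin_req <- if (setting %in% c("SoSt", "SoWt", "WoSt")) 6L else 8L
  if (p < pmin_req) stop("setting ", setting, " requires p >= ", pmin_req)
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (n < 2) stop("n must be >= 2")
  funs <- sim_mean_funs(setting)
  with_seed(seed, {
    z <- matrix(rnorm(n * p), n, p)
    if (rho > 0) {
      f <- rnorm(n)
      z <- sqrt(rho) * f + sqrt(1 - rho) * z
    }
    colnames(z) <- paste0("Z", seq_len(p))
    t <- funs$m(z) + rnorm(n)
    y <- eta * t + funs$g(z) + rnorm(n)
    structure(list(t = t, y = y, z = z, setting = setting, n = n, p = p,
                   rho = rho, eta = eta, seed = seed),
              class = "trisample")
  })
}

#' @method print trisample
#' @export
print.trisample <- function(x, ...) {
  cat("trisample: n =", x$n, ", p =", x$p,
      if (!is.null(x$setting)) paste0("(", x$setting, ", rho = ", x$rho,
                                      ", eta = ", x$eta, ")"), "\n")
  invisible(x)
}

resolve_cell_method <- function(method) {
  if (is.function(method)) return(method)
  switch(match.arg(method, c("goaldr", "sldr", "select")),
    goaldr = function(d, control, boot, boot_B) {
      f <- goaldr(d$t, d$y, d$z, control = control)
      res <- list(slope = f$slope, analytic_sd = f$analytic_sd,
                  selected = f$selected)
      if (boot) res$boot <- drf_boot(f, B = boot_B, seed = control$seed)
      res
    },
    sldr = function(d, control, boot, boot_B) {
      f <- sldr(d$t, d$y, d$z, control = control)
      res <- list(slope = f$slope, analytic_sd = f$analytic_sd)
      if (boot) res$boot <- drf_boot(f, B = boot_B, seed = control$seed)
      res
    },
    select = function(d, control, boot, boot_B) {
      s <- goaldr_select(d$t, d$y, d$z, control = control)
      list(slope = NA_real_, analytic_sd = NA_real_,
           selected = s$selected)
    })
}

#' Run one Monte-Carlo cell
#'
#' Generates `replicates` fresh datasets (seed = `seed + replicate
#' index`), fits the requested method on each, and summarizes: mean
#' estimate, empirical SD, mean analytic SE, coverage of the 95% CI,
#' power of the Wald test of zero slope, and RMSE
#' \eqn{\sqrt{B^{-1}\sum_b (\hat\eta_b - \eta)^2}}.
#'
#' @param setting,n,p,rho,eta passed to [sim_drf_data()].
#' @param method `"goaldr"`, `"sldr"`, `"select"` (selection only, no
#'   dose-response estimate), or a function `(data, control, boot,
#'   boot_B)` returning a list with `slope`, `analytic_sd`, optionally
#'   `selected` and `boot`.
#' @param replicates number of Monte-Carlo replicates (>= 2).
#' @param seed base seed; replicate r uses `seed + r`.
#' @param control a [goaldr_control()] list.
#' @param boot if `TRUE`, run the bootstrap inside every replicate (slow)
#'   and add `boot_std` / bootstrap-coverage summaries.
#' @param boot_B bootstrap replicates per Monte-Carlo replicate.
#' @return Object of class `"sim_cell"`: list with `replicates`
#'   (per-replicate data.frame), `selection` (replicate x covariate 0/1
#'   matrix, when available), `summary` (one-row data.frame), and the
#'   cell configuration.
#' @export
simulate_cell <- function(setting = "SoSt", n = 200, p = 20, rho = 0,
                          eta = 2, method = "goaldr", replicates = 100,
                          seed = 1L, control = goaldr_control(),
                          boot = FALSE, boot_B = 100L) {
  if (replicates < 2) stop("replicates must be >= 2")
  control <- as_goaldr_control(control)
  fn <- resolve_cell_method(method)
  res <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    d <- sim_drf_data(setting, n, p, rho, eta, seed = seed + r)
    res[[r]] <- tryCatch(fn(d, control, boot, boot_B),
                         error = function(e) e)
  }
  errs <- vapply(res, inherits, logical(1), "error")
  if (any(errs)) {
    warning(sum(errs), " of ", replicates, " replicates failed; first: ",
            conditionMessage(res[[which(errs)[1]]]))
    if (sum(errs) > 0.1 * replicates)
      stop("more than 10% of replicates failed")
  }
  ok <- res[!errs]
  reps <- data.frame(
    replicate = which(!errs),
    slope = vapply(ok, function(r) r$slope %||% NA_real_, numeric(1)),
    analytic_sd = vapply(ok, function(r) r$analytic_sd %||% NA_real_,
                         numeric(1)))
  if (boot) {
    reps$boot_sd <- vapply(ok, function(r)
      if (is.null(r$boot)) NA_real_ else r$boot$boot_sd, numeric(1))
    blo <- vapply(ok, function(r)
      if (is.null(r$boot)) NA_real_ else r$boot$percentile_ci[1], numeric(1))
    bhi <- vapply(ok, function(r)
      if (is.null(r$boot)) NA_real_ else r$boot$percentile_ci[2], numeric(1))
    reps$boot_cover <- as.numeric(blo <= eta & eta <= bhi)
  }
  selection <- NULL
  if (!is.null(ok[[1]]$selected)) {
    selection <- t(vapply(ok, function(r) {
      v <- numeric(p); v[r$selected] <- 1; v
    }, numeric(p)))
    colnames(selection) <- paste0("Z", seq_len(p))
  }
  zq <- qnorm(0.975)
  est <- reps$slope; se <- reps$analytic_sd
  have_est <- !all(is.na(est))
  summary <- data.frame(
    setting = setting, n = n, p = p, rho = rho, eta = eta,
    method = if (is.function(method)) "custom" else method,
    replicates = nrow(reps),
    est = if (have_est) mean(est) else NA_real_,
    emp_std = if (have_est) sd(est) else NA_real_,
    est_std = if (have_est) mean(se) else NA_real_,
    boot_std = if (boot) mean(reps$boot_sd, na.rm = TRUE) else NA_real_,
    coverage = if (have_est)
      mean(abs(est - eta) <= zq * se) else NA_real_,
    boot_coverage = if (boot) mean(reps$boot_cover, na.rm = TRUE)
      else NA_real_,
    power = if (have_est) mean(abs(est) / se > zq) else NA_real_,
    rmse = if (have_est) sqrt(mean((est - eta)^2)) else NA_real_)
  structure(list(replicates = reps, selection = selection,
                 summary = summary, setting = setting, n = n, p = p,
                 rho = rho, eta = eta, seed = seed),
            class = "sim_cell")
}

#' @method print sim_cell
#' @export
print.sim_cell <- function(x, ...) {
  cat("Monte-Carlo cell:", x$setting, "n =", x$n, "p =", x$p,
      "rho =", x$rho, "eta =", x$eta, "\n")
  print(x$summary[, -(1:5)], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Covariate selection proportions
#'
#' Per-covariate fraction of replicates in which each covariate entered
#' the final selected set, with grouped summaries over the confounder /
#' prognostic / instrumental / spurious roles of the generating setting.
#'
#' @param cell a `"sim_cell"` with selection indicators.
#' @return list with `per_covariate` (named vector) and `groups`
#'   (data.frame of group means).
#' @export
selection_proportions <- function(cell) {
  if (!inherits(cell, "sim_cell") || is.null(cell$selection))
    stop("'cell' must be a sim_cell with selection indicators")
  per <- colMeans(cell$selection)
  roles <- sim_roles(cell$setting, cell$p)
  groups <- data.frame(
    group = names(roles),
    covariates = vapply(roles, function(i)
      paste0("Z", i[1], "-Z", i[length(i)]), character(1)),
    mean_proportion = vapply(roles, function(i)
      if (length(i)) mean(per[i]) else NA_real_, numeric(1)),
    row.names = NULL)
  list(per_covariate = per, groups = groups)
}
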