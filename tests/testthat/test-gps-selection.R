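test_that("gamma-lambda coupling follows the closed form and rejects
           gamma <= 1", {
  expect_equal(gamma_for_lambda(-1), 8)
  expect_equal(gamma_for_lambda(0.49), 5.02)
  expect_equal(gamma_for_lambda(-10), 26)
  expect_error(gamma_for_lambda(2.5), "gamma <= 1")
  g <- lambda_grid(500)
  expect_true(all(g$gamma > 1))
  expect_equal(g$lambda, 500^g$exponent)
  # lambda_n * n^(gamma/2 - 1) = n^2 on the whole grid
  expect_equal(log(g$lambda, 500) + g$gamma / 2 - 1, rep(2, nrow(g)),
               tolerance = 1e-12)
})

test_that("penalty weights follow the inverse-relevance formula", {
  pw <- penalty_weights(matrix(rnorm(20), 20, 1), gamma = 3,
                        dcor_raw = 0.3, y = NULL, t = NULL)
  expect_identical(pw$w_hat, 1)
  pw2 <- penalty_weights(matrix(rnorm(40), 20, 2), gamma = 2,
                         dcor_raw = c(0.4, 0.2), y = NULL, t = NULL)
  expect_equal(pw2$w_hat, c(1, 4))
  pw3 <- penalty_weights(matrix(rnorm(40), 20, 2), gamma = 2,
                         dcor_raw = c(0.4, 0.2), direction = "literal",
                         y = NULL, t = NULL)
  expect_equal(pw3$w_hat, c(1, 0.25))
  pw4 <- penalty_weights(matrix(rnorm(60), 20, 3), gamma = 2,
                         dcor_raw = c(0.5, 0, 0.1), y = NULL, t = NULL)
  expect_identical(pw4$w_hat[2], Inf)
  expect_error(penalty_weights(matrix(rnorm(40), 20, 2), gamma = 2,
                               dcor_raw = c(0, 0), y = NULL, t = NULL),
               "no covariate related to outcome")
  # monotone: stronger outcome relation never penalized more
  d <- sort(runif(6, 0.01, 0.9))
  w <- penalty_weights(matrix(rnorm(120), 20, 6), gamma = 4,
                       dcor_raw = d, y = NULL, t = NULL)$w_hat
  expect_true(all(diff(w) <= 1e-12))
})

test_that("weighted lasso: unpenalized limit, full shrinkage, objective
           optimality, and KKT conditions", {
  set.seed(121)
  n <- 50; p <- 5
  z <- matrix(rnorm(n * p), n, p)
  t <- z[, 1] - 0.7 * z[, 3] + rnorm(n)
  w_hat <- c(1, 2, 1, 5, 10)
  f0 <- weighted_lasso(z, t, rep(1, p), 0)
  expect_equal(unname(f0$coef), unname(coef(lm(t ~ z))[-1]),
               tolerance = 1e-6)
  fh <- weighted_lasso(z, t, rep(1, p), n^10)
  expect_length(fh$active, 0)
  lam <- 4
  fit <- weighted_lasso(z, t, w_hat, lam)
  zs <- scale(z)
  obj_std <- function(b) sum((t - mean(t) - zs %*% b)^2) +
    lam * sum(w_hat * abs(b))
  ols_b <- drop(solve(crossprod(zs), crossprod(zs, t - mean(t))))
  expect_lte(obj_std(fit$coef_std), obj_std(ols_b) + 1e-8)
  expect_lte(obj_std(fit$coef_std), obj_std(numeric(p)) + 1e-8)
  # KKT: |2 z_j'r| = lam w_j on the active set, <= lam w_j off it
  r <- drop(t - mean(t) - zs %*% fit$coef_std)
  gsub <- drop(2 * crossprod(zs, r))
  for (j in seq_len(p)) {
    if (fit$coef_std[j] != 0)
      expect_lt(abs(gsub[j] - lam * w_hat[j] * sign(fit$coef_std[j])),
                1e-6)
    else expect_lte(abs(gsub[j]), lam * w_hat[j] + 1e-6)
  }
})

test_that("weighted lasso agrees with the reparameterized glmnet solve", {
  set.seed(131)
  n <- 80; p <- 5
  z <- matrix(rnorm(n * p), n, p)
  t <- z[, 1] + 0.5 * z[, 2] + rnorm(n)
  w_hat <- c(1, 2, 4, 8, 16)
  lam <- 3
  fit <- weighted_lasso(z, t, w_hat, lam)
  zs <- scale(z)
  zt <- sweep(zs, 2, w_hat, "/")
  gl <- glmnet::glmnet(zt, t - mean(t), lambda = lam / (2 * n),
                       standardize = FALSE, intercept = FALSE,
                       thresh = 1e-14)
  b_or <- as.numeric(coef(gl))[-1] / w_hat
  expect_equal(unname(fit$coef_std), b_or, tolerance = 1e-7)
})

test_that("infinite penalty weights exclude covariates deterministically", {
  set.seed(141)
  n <- 60
  z <- matrix(rnorm(n * 3), n, 3)
  t <- z[, 1] + rnorm(n)
  fit <- weighted_lasso(z, t, c(1, Inf, 2), 0.5)
  expect_identical(unname(fit$coef[2]), 0)
  expect_false(2 %in% fit$active)
})

test_that("selection path has the grid shape and a single-lambda = 0 grid
           reduces to least squares", {
  set.seed(151)
  d <- sim_drf_data("SoSt", n = 120, p = 8, seed = 7)
  p0 <- selection_path(d$t, d$y, d$z, exponents = -10)
  expect_length(p0$records, 1)
  # the single record reproduces a direct weighted-lasso solve with the
  # coupled gamma and the path's cached outcome relevances
  pw <- penalty_weights(d$z, gamma = gamma_for_lambda(-10),
                        dcor_raw = p0$dcor_raw, y = NULL, t = NULL)
  direct <- weighted_lasso(d$z, d$t, pw, 120^-10)
  expect_equal(p0$records[[1]]$coef, direct$coef, tolerance = 1e-8)
  pth <- selection_path(d$t, d$y, d$z)
  expect_length(pth$records, 10)
  expect_true(all(is.finite(pth$summary$size)))
  expect_identical(pth$summary$size,
                   vapply(pth$records, function(r) length(r$active),
                          integer(1)))
})

test_that("outcome-related covariates are penalized less than instruments
           and spurious covariates on simulated confounded data", {
  runs <- sost_select_runs()
  med_rel <- vapply(runs, function(r)
    median(r$path$dcor_raw[1:4]), numeric(1))
  med_irr <- vapply(runs, function(r)
    median(r$path$dcor_raw[5:20]), numeric(1))
  expect_true(all(med_rel > med_irr))
  # and the mid-path active sets keep confounders while dropping IVs
  hit <- vapply(runs, function(r) {
    any(vapply(r$path$records, function(rec)
      all(c(1, 2) %in% rec$active) && !any(c(5, 6) %in% rec$active),
      logical(1)))
  }, logical(1))
  expect_gte(mean(hit), 0.8)
})
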