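test_that("pseudo-outcome collapses to the truth with an exact outcome
           model and to Y with a null model", {
  set.seed(271)
  n <- 20
  t <- rnorm(n)
  y <- 2 * t
  z <- matrix(rnorm(n * 2), n)
  w <- rand_weights(n)
  mu_exact <- function(z, t) 2 * t
  ps <- build_pseudo_outcome(mu_exact, t, y, z, w)
  expect_equal(ps$theta, 2 * t, tolerance = 1e-12)
  mu_zero <- function(z, t) rep(0, length(t))
  y2 <- rnorm(n)
  ps2 <- build_pseudo_outcome(mu_zero, t, y2, z, rep(1, n))
  expect_equal(ps2$theta, y2, tolerance = 1e-12)
})

test_that("pseudo-outcome matches the double-loop oracle and recomposes
           exactly", {
  set.seed(281)
  n <- 6
  t <- c(0.3, -1, 2, 0.7, -0.2, 1.4)
  y <- c(1, 0, 3, 2, -1, 0.5)
  z <- matrix(c(1, 2, 0, -1, 0.5, 3, -2, 1, 0, 2, 1, -1), n, 2)
  w <- rand_weights(n)
  mu <- function(zrow, t) 0.5 * sum(zrow) + 1.5 * t
  mu_vec <- function(z, t) {
    if (is.null(z)) rep(0, length(t)) else drop(0.5 * rowSums(z) + 1.5 * t)
  }
  ps <- build_pseudo_outcome(mu_vec, t, y, z, w)
  expect_equal(ps$theta, bf_pseudo(mu, t, y, z, w), tolerance = 1e-10)
  expect_equal(ps$theta, ps$term1 + ps$term2, tolerance = 1e-12)
})

test_that("dose-response regression recovers exact lines and matches the
           closed-form OLS slope and standard error", {
  t <- seq(-2, 2, length.out = 10)
  r <- suppressWarnings(regress_drf(2 * t, t))
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  r0 <- suppressWarnings(regress_drf(rep(5, 10), t))
  expect_equal(r0$slope, 0, tolerance = 1e-12)
  set.seed(291)
  theta <- 1 + 0.5 * t + rnorm(10)
  r1 <- regress_drf(theta, t)
  o <- bf_ols_slope(theta, t)
  expect_equal(r1$slope, o[["slope"]], tolerance = 1e-10)
  expect_equal(r1$intercept, o[["intercept"]], tolerance = 1e-10)
  expect_equal(r1$analytic_sd, o[["se"]], tolerance = 1e-10)
  expect_equal(unname(r1$ci["upper"] - r1$slope),
               qnorm(0.975) * r1$analytic_sd, tolerance = 1e-12)
  expect_error(regress_drf(theta, rep(1, 10)), "constant")
})

test_that("the fitters validate their inputs and are deterministic under a
           fixed seed", {
  d <- sim_drf_data("SoSt", n = 80, p = 6, seed = 31)
  expect_error(goaldr(d$t, d$y, NULL), "no covariates")
  expect_error(goaldr(d$t[1:20], d$y[1:20], d$z[1:20, ]), "n >= 30")
  ctl <- fast_ctl()
  f1 <- goaldr(d$t, d$y, d$z, control = ctl)
  f2 <- goaldr(d$t, d$y, d$z, control = ctl)
  expect_identical(f1$slope, f2$slope)
  expect_identical(f1$selected, f2$selected)
  s1 <- sldr(d$t, d$y, d$z, control = ctl)
  s2 <- sldr(d$t, d$y, d$z, control = ctl)
  expect_identical(s1$slope, s2$slope)
  expect_s3_class(f1, "drf_fit")
  expect_identical(f1$method, "GOALDeR")
  expect_identical(s1$method, "SL-DR")
})

test_that("model-object methods behave like a classic fit object", {
  d <- sim_drf_data("SoSt", n = 80, p = 6, seed = 33)
  f <- goaldr(d$t, d$y, d$z, control = fast_ctl())
  expect_output(print(f), "GOALDeR dose-response fit")
  expect_output(print(summary(f)), "balance")
  expect_length(coef(f), 2)
  expect_equal(unname(predict(f, c(0, 1))),
               unname(c(coef(f)[1], sum(coef(f)))), tolerance = 1e-10)
  expect_length(residuals(f), 80)
  ci <- confint(f)
  expect_lt(ci[1], ci[2])
})

test_that("treatment independent of covariates: SL-DR weights are near one
           and the slope is recovered", {
  set.seed(301)
  ok <- replicate(5, {
    n <- 150
    z <- matrix(rnorm(n * 4), n)
    t <- rnorm(n)
    y <- 2 * t + rnorm(n, sd = 0.5)
    f <- sldr(t, y, z, control = fast_ctl())
    abs(f$slope - 2) < 0.2 && mean(abs(f$weights - 1)) < 0.5
  })
  expect_gte(mean(ok), 0.8)
})

test_that("bootstrap: near-degenerate data give a tiny SD, noisy data a
           positive one, and a fixed seed reproduces it", {
  set.seed(311)
  n <- 200
  z <- matrix(rnorm(n * 4), n)
  t <- rnorm(n)
  y <- 2 * t                       # no noise
  f <- goaldr(t, y, z, control = fast_ctl())
  b <- drf_boot(f, B = 50, seed = 9)
  expect_lt(b$boot_sd, 0.02)
  expect_gt(b$boot_sd, 0)
  b2 <- drf_boot(f, B = 10, seed = 123)
  b3 <- drf_boot(f, B = 10, seed = 123)
  expect_identical(b2$boot_sd, b3$boot_sd)
  expect_error(drf_boot(f, B = 1), "B must be")
  expect_true(b$percentile_ci[1] <= b$percentile_ci[2])
})
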