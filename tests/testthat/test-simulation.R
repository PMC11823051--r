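test_that("generator moments match their closed forms at large n", {
  d <- sim_drf_data("SoSt", n = 20000, p = 6, rho = 0, eta = 2, seed = 41)
  # T = Z1+Z2+Z5+Z6+noise: Var 5, corr(T, Z1) = 1/sqrt(5)
  expect_equal(var(d$t), 5, tolerance = 0.1)
  expect_equal(cor(d$t, d$z[, 1]), 1 / sqrt(5), tolerance = 0.02)
  expect_equal(cor(d$t, d$z[, 3]), 0, tolerance = 0.02)
  d2 <- sim_drf_data("SoSt", n = 20000, p = 6, rho = 0.5, seed = 42)
  expect_equal(cov(d2$z[, 1], d2$z[, 2]), 0.5, tolerance = 0.02)
  expect_equal(var(d2$z[, 4]), 1, tolerance = 0.03)
  # eta = 0: no partial treatment effect given the outcome covariates
  d3 <- sim_drf_data("SoSt", n = 20000, p = 6, rho = 0, eta = 0, seed = 43)
  cf <- coef(lm(d3$y ~ d3$t + d3$z[, 1:4]))[["d3$t"]]
  expect_equal(cf, 0, tolerance = 0.03)
})

test_that("the nonlinear settings wire the stated mean structures", {
  d <- sim_drf_data("CoMt", n = 5000, p = 8, rho = 0, eta = 2, seed = 44)
  z <- d$z
  m <- exp(z[, 1] / 2) + (z[, 2] / (1 + exp(z[, 1])) + 10) +
    (0.04 * z[, 1] * z[, 3] + 0.6)^3 + (z[, 2] + z[, 4])^2 +
    z[, 7] + z[, 8]
  expect_equal(var(d$t - m), 1, tolerance = 0.05)
  expect_equal(var(d$y - 2 * d$t - rowSums(z[, 1:6])), 1, tolerance = 0.05)
  d2 <- sim_drf_data("MoCt", n = 5000, p = 8, seed = 45)
  m2 <- rowSums(d2$z[, c(1:4, 7, 8)])
  expect_equal(var(d2$t - m2), 1, tolerance = 0.05)
  expect_error(sim_drf_data("MoMt", n = 100, p = 7), "p >= 8")
  expect_error(sim_drf_data("SoSt", n = 100, p = 5), "p >= 6")
})

test_that("the same seed reproduces a dataset bit for bit", {
  a <- sim_drf_data("MoMt", n = 50, p = 9, rho = 0.2, eta = 0.4, seed = 5)
  b <- sim_drf_data("MoMt", n = 50, p = 9, rho = 0.2, eta = 0.4, seed = 5)
  expect_identical(a$z, b$z)
  expect_identical(a$t, b$t)
  expect_identical(a$y, b$y)
})

test_that("a constant stub method produces the degenerate cell summary", {
  stub <- function(d, control, boot, boot_B)
    list(slope = 2, analytic_sd = 0.1)
  cell <- simulate_cell("SoSt", n = 50, p = 6, eta = 2, method = stub,
                        replicates = 20, seed = 1)
  s <- cell$summary
  expect_equal(s$est, 2)
  expect_equal(s$emp_std, 0)
  expect_equal(s$coverage, 1)
  expect_equal(s$power, 1)
  expect_equal(s$rmse, 0)
})

test_that("a calibrated noisy stub yields nominal-range coverage and the
           RMSE identity holds on every cell", {
  stub <- function(d, control, boot, boot_B)
    list(slope = d$eta + rnorm(1, sd = 0.05), analytic_sd = 0.05)
  cell <- simulate_cell("SoSt", n = 50, p = 6, eta = 2, method = stub,
                        replicates = 200, seed = 7)
  expect_gt(cell$summary$coverage, 0.90)
  expect_lt(cell$summary$coverage, 0.99)
  B <- cell$summary$replicates
  bias <- cell$summary$est - 2
  expect_equal(cell$summary$rmse^2,
               bias^2 + cell$summary$emp_std^2 * (B - 1) / B,
               tolerance = 1e-10)
})

test_that("selection bookkeeping: indicators and grouped proportions", {
  stub <- function(d, control, boot, boot_B)
    list(slope = 2, analytic_sd = 0.1, selected = c(1L, 2L))
  cell <- simulate_cell("SoSt", n = 50, p = 8, method = stub,
                        replicates = 5, seed = 2)
  sp <- selection_proportions(cell)
  expect_equal(unname(sp$per_covariate), c(1, 1, rep(0, 6)))
  g <- sp$groups
  expect_equal(g$mean_proportion[g$group == "confounder"], 1)
  expect_equal(g$mean_proportion[g$group == "instrument"], 0)
  cell2 <- simulate_cell("SoSt", n = 50, p = 6, method = function(...)
    list(slope = 2, analytic_sd = 1), replicates = 3, seed = 2)
  expect_error(selection_proportions(cell2), "selection indicators")
})

test_that("cells are reproducible and failures beyond 10% abort the cell", {
  stub <- function(d, control, boot, boot_B)
    list(slope = mean(d$y), analytic_sd = sd(d$y))
  c1 <- simulate_cell("SoWt", n = 40, p = 6, method = stub,
                      replicates = 5, seed = 11)
  c2 <- simulate_cell("SoWt", n = 40, p = 6, method = stub,
                      replicates = 5, seed = 11)
  expect_identical(c1$summary, c2$summary)
  flaky <- function(d, control, boot, boot_B) {
    if (d$seed %% 2 == 0) stop("boom")
    list(slope = 2, analytic_sd = 0.1)
  }
  expect_error(
    suppressWarnings(simulate_cell("SoSt", n = 40, p = 6, method = flaky,
                                   replicates = 10, seed = 1)),
    "10%")
})
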