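test_that("distance correlation matches the brute-force double-sum oracle", {
  expect_equal(dcor(0:4, c(1, 0, 3, 2, 5)),
               bf_dcor(0:4, c(1, 0, 3, 2, 5)), tolerance = 1e-10)
  set.seed(11)
  for (n in c(5, 8, 12)) {
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(dcor(x, y), bf_dcor(x, y), tolerance = 1e-10)
  }
})

test_that("degenerate and invalid inputs follow the conventions", {
  expect_identical(dcor(1:5, 1:5), 1)
  expect_identical(dcor(rep(2, 5), c(1, 0, 3, 2, 5)), 0)
  expect_identical(dcor(c(1, 0, 3, 2, 5), rep(0, 5)), 0)
  expect_error(dcor(1:3, 1:3), "invalid sample")
  expect_error(dcor(c(1, NA, 3, 4), 1:4), "non-finite")
  expect_error(wdcov_sq(1:5, 1:5, rep(1, 4)), "length")
  expect_error(wdcor(1:5, 1:5, c(-1, 2, 1, 1, 2)), "nonnegative")
  expect_error(wdcor(1:5, 1:5, rep(2, 5)), "sum to the sample size")
})

test_that("dcor is symmetric and affine invariant", {
  set.seed(21)
  for (r in 1:5) {
    x <- rnorm(9); y <- rnorm(9)
    expect_equal(dcor(x, y), dcor(y, x), tolerance = 1e-12)
    expect_equal(dcor(3.2 * x - 7, -0.5 * y + 2), dcor(x, y),
                 tolerance = 1e-9)
  }
})

test_that("weighted statistics match the loop oracle and reduce to the
           unweighted case under uniform weights", {
  set.seed(31)
  x6 <- rnorm(6); y6 <- rnorm(6); w6 <- rand_weights(6)
  expect_equal(wdcov_sq(x6, y6, w6), bf_dcov_stats(x6, y6, w6)[["dcov2"]],
               tolerance = 1e-10)
  x8 <- rnorm(8); y8 <- rnorm(8); w8 <- rand_weights(8)
  expect_equal(wdcor(x8, y8, w8), bf_dcor(x8, y8, w8), tolerance = 1e-10)
  expect_equal(wdcov_sq(x8, y8, rep(1, 8)),
               bf_dcov_stats(x8, y8)[["dcov2"]], tolerance = 1e-10)
  expect_equal(wdcor(x8, y8, rep(1, 8)), dcor(x8, y8), tolerance = 1e-10)
  expect_identical(wdcor(x8, x8, w8), 1)
  expect_gte(wdcov_sq(x8, x8, w8), 0)
})

test_that("distance correlation of independent Gaussians concentrates near
           zero at n = 1000", {
  set.seed(41)
  vals <- replicate(100, dcor(rnorm(1000), rnorm(1000)))
  expect_gte(mean(vals < 0.1), 0.95)
})

test_that("conditional dcor separates conditional dependence from
           independence", {
  set.seed(51)
  ind <- replicate(20, {
    n <- 500
    cdcor(rnorm(n), rnorm(n), rnorm(n))
  })
  expect_lt(mean(ind), 0.1)
  dep <- replicate(5, {
    n <- 500
    z <- rnorm(n)
    cdcor(z, z, rnorm(n))
  })
  expect_gt(mean(dep), 0.5)
})

test_that("conditional dcor conventions: degenerate variables and
           constant conditioning", {
  set.seed(61)
  y <- rnorm(30); t <- rnorm(30)
  expect_identical(cdcor(rep(1, 30), y, t), 0)
  z0 <- y + rnorm(30)
  expect_warning(v <- cdcor(z0, y, rep(2, 30)), "constant")
  expect_equal(v, dcor(z0, y), tolerance = 1e-12)
  z <- rnorm(200); yy <- z + rnorm(200); tt <- rnorm(200)
  expect_equal(cdcor(5 * z - 1, -2 * yy + 3, tt), cdcor(z, yy, tt),
               tolerance = 1e-8)
  expect_error(cdcor(rnorm(8), rnorm(8), rnorm(8)), "n >= 10")
})
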