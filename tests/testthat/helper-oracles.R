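# Brute-force oracles, written straight from the definitions and kept
# independent of the package's computational kernels.

# O(n^2) double-sum distance-covariance statistics with explicit
# (unweighted) double centering; weights enter only the quadratic form.
bf_dcov_stats <- function(x, y, w = rep(1, length(x))) {
  n <- length(x)
  ctr <- function(M)
    M - outer(rowMeans(M), rep(1, n)) - outer(rep(1, n), colMeans(M)) +
      mean(M)
  A <- ctr(abs(outer(x, x, "-")))
  B <- ctr(abs(outer(y, y, "-")))
  sab <- 0; saa <- 0; sbb <- 0
  for (i in seq_len(n))
    for (j in seq_len(n)) {
      ww <- w[i] * w[j]
      sab <- sab + ww * A[i, j] * B[i, j]
      saa <- saa + ww * A[i, j]^2
      sbb <- sbb + ww * B[i, j]^2
    }
  c(dcov2 = sab, dvarx = saa, dvary = sbb) / n^2
}

bf_dcor <- function(x, y, w = rep(1, length(x))) {
  s <- bf_dcov_stats(x, y, w)
  den <- sqrt(s[["dvarx"]] * s[["dvary"]])
  if (den <= 0) return(0)
  r2 <- s[["dcov2"]] / den
  if (r2 <= 0) 0 else sqrt(min(r2, 1))
}

# closed-form simple-regression slope and its conventional SE
bf_ols_slope <- function(y, x) {
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  rss <- sum((y - a - b * x)^2)
  se <- sqrt(rss / (n - 2) / sum((x - mean(x))^2))
  c(slope = b, intercept = a, se = se)
}

# random weight vector satisfying the sum-to-n constraint
rand_weights <- function(n) {
  w <- runif(n, 0.2, 2)
  n * w / sum(w)
}

# double-loop pseudo-outcome oracle for an explicit mu(z-row, t) function
bf_pseudo <- function(mu, t, y, z, w) {
  n <- length(t)
  theta <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (k in seq_len(n)) s <- s + mu(z[k, ], t[i])
    theta[i] <- s / n + (y[i] - mu(z[i, ], t[i])) * w[i]
  }
  theta
}
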