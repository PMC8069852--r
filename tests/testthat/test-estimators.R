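test_that("pearson correlation matches the closed formula and handles errors", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 4)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(fc_pearson(x, y), hand)
  z <- rnorm(100)
  expect_equal(fc_pearson(z, z), 1)
  expect_equal(fc_pearson(z, -z), -1)
  set.seed(1)
  expect_lt(abs(fc_pearson(rnorm(1000), rnorm(1000))), 0.1)
  expect_error(fc_pearson(rep(1, 10), rnorm(10)), "constant")
  expect_error(fc_pearson(rnorm(5), rnorm(6)), "equal length")
})

test_that("delayed correlation recovers shifts, signs and the exhaustive optimum", {
  set.seed(2)
  s <- rnorm(1100)
  x <- s[6:1005]; y <- s[1:1000]          # y[n] = x[n - 5]
  r <- fc_delayed_correlation(x, y)
  expect_equal(r$delay, 5)
  expect_gt(r$value, 0.999)
  r2 <- fc_delayed_correlation(s[4:1003], -s[1:1000])
  expect_equal(r2$delay, 3)
  expect_lt(r2$value, -0.999)
  # lag-2 AR coupling: compare against a brute-force scan over all delays
  cp <- sim_coupled(1000, d = 2)
  r3 <- fc_delayed_correlation(cp$x, cp$y, max_delay = 30)
  brute <- sapply(0:30, function(d) {
    n <- length(cp$x)
    cor(cp$x[1:(n - d)], cp$y[(1 + d):n])
  })
  expect_equal(r3$delay, which.max(abs(brute)) - 1L)
  expect_equal(r3$value, brute[r3$delay + 1L])
  expect_error(fc_delayed_correlation(rnorm(60), rnorm(60), max_delay = 40),
               "half")
})

test_that("coherence is 1 for identical signals and ~0.5 at per-frequency SNR 1", {
  set.seed(3)
  x <- rnorm(1000)
  co <- fc_coherence(x, x)
  expect_true(all(abs(co$value - 1) < 1e-8))
  # independent noise: small, and smaller with more data (estimator bias)
  c_short <- band_average(co$f, fc_coherence(rnorm(300), rnorm(300))$value)
  c_long <- band_average(co$f, fc_coherence(rnorm(3000), rnorm(3000))$value)
  expect_lt(c_long, c_short)
  toy <- make_fixtures(seed = 4)$snr1
  cb <- fc_coherence(toy$x, toy$y)
  in_band <- band_average(cb$f, cb$value, band = toy$truth$band)
  expect_equal(in_band, 0.5, tolerance = 0.15)
})

test_that("lagged coherence suppresses zero-lag mixing but keeps lagged coupling", {
  set.seed(4)
  x <- as.numeric(stats::arima.sim(list(ar = 0.8), 1000))
  expect_warning(lc <- fc_lagged_coherence(x, 2 * x), "degenerate")
  expect_lt(band_average(lc$f, lc$value), 0.02)
  # quadrature pair: cross-spectrum purely imaginary, so LC ~ coherence
  n <- 1000
  tt <- seq_len(n) / 100
  ph <- cumsum(rnorm(n, 0, 0.02))
  xs <- sin(2 * pi * 10 * tt + ph)
  ys <- cos(2 * pi * 10 * tt + ph)
  co <- fc_coherence(xs, ys); lcq <- fc_lagged_coherence(xs, ys)
  i10 <- which.min(abs(co$f - 10))
  expect_equal(lcq$value[i10], co$value[i10], tolerance = 0.05)
  ind <- fc_lagged_coherence(rnorm(1000), rnorm(1000))
  expect_lt(band_average(ind$f, ind$value), 0.15)
})

test_that("phase synchronization behaves like the averaged unit phasor", {
  n <- 1000; tt <- seq_len(n) / 100
  x <- sin(2 * pi * 10 * tt)
  expect_equal(fc_phase_sync(x, x), 1, tolerance = 1e-6)
  y90 <- sin(2 * pi * 10 * tt + pi / 2)
  expect_equal(fc_phase_sync(x, y90), 1, tolerance = 1e-3)
  # 10 vs 11 Hz: phasor rotates uniformly, average collapses
  y11 <- sin(2 * pi * 11 * tt)
  expect_lt(fc_phase_sync(x, y11), 0.1)
  # symmetry
  set.seed(6)
  a <- rnorm(500); b <- rnorm(500)
  expect_identical(fc_phase_sync(a, b), fc_phase_sync(b, a))
})

test_that("AR fitting recovers known coefficients and nests residual variances", {
  set.seed(7)
  y <- as.numeric(stats::arima.sim(list(ar = c(0.6, -0.3)), 1000))
  x <- rnorm(1000)
  fit <- fit_ar(x, y, p = 2)
  expect_equal(unname(fit$a["y", ]), c(0.6, -0.3), tolerance = 0.12)
  # cross coefficients from independent x are negligible
  expect_lt(max(abs(fit$A[2, 1, ])), 0.1)
  # in-sample nesting: bivariate residual variance <= univariate
  for (p in c(2, 5, 10)) {
    f <- fit_ar(x, y, p = p)
    expect_lte(f$Sigma[2, 2], f$gamma["y"])
    expect_lte(f$Sigma[1, 1], f$gamma["x"])
  }
  expect_true(all(eigen(fit$Sigma)$values > -1e-12))
})

test_that("temporal Granger equals a brute-force two-regression oracle", {
  set.seed(8)
  cp <- sim_coupled(1000)
  for (p in c(3, 5, 12)) {
    expect_equal(fc_granger_time(cp$x, cp$y, p = p),
                 gc_brute(cp$x, cp$y, p), tolerance = 1e-10)
  }
  # directionality of the construction
  gc_fwd <- fc_granger_time(cp$x, cp$y, p = 5)
  gc_rev <- fc_granger_time(cp$y, cp$x, p = 5)
  expect_gt(gc_fwd, 0.5)
  expect_lt(gc_rev, 0.05)
  # null pairs: in-sample bias is O(p/N)
  nl <- fc_granger_time(rnorm(1000), rnorm(1000), p = 5)
  expect_lt(nl, 0.05)
  expect_gte(nl, 0)
})

test_that("temporal Granger matches the closed-form value on a known VAR(1)", {
  # y[n] = 0.5 y[n-1] + 0.4 x[n-1] + e, x[n] = 0.9 x[n-1] + u
  # restricted model of y is ARMA; solve its AR(inf) residual variance by
  # long Yule-Walker truncation for the oracle
  set.seed(9)
  A <- matrix(c(0.9, 0, 0.4, 0.5), 2, 2, byrow = TRUE)
  X <- sim_var1(50000, A)
  p <- 30
  gc_est <- fc_granger_time(X[, 1], X[, 2], p = p)
  oracle <- gc_brute(X[, 1], X[, 2], p)
  expect_equal(gc_est, oracle, tolerance = 1e-10)
  expect_gt(gc_est, 0.1)
})

test_that("spectral Granger peaks at the coupling frequency and integrates to GC", {
  set.seed(10)
  n <- 2000
  # oscillatory source at ~10 Hz driving y
  x <- as.numeric(stats::arima.sim(list(ar = c(2 * 0.95 * cos(2 * pi * 10 / 100),
                                               -0.95^2)), n))
  y <- numeric(n); e <- rnorm(n)
  for (t in 3:n) y[t] <- 0.3 * y[t - 1] + 0.8 * x[t - 1] + e[t]
  sg <- fc_granger_spectral(x, y, p = 8)
  expect_equal(sg$f[which.max(sg$value)], 10, tolerance = 1)
  rev <- fc_granger_spectral(y, x, p = 8)
  expect_lt(mean(rev$value), 0.1 * mean(sg$value))
  expect_true(all(sg$value >= 0))
  # Geweke identity: mean over the full band ~ temporal GC
  gc <- fc_granger_time(x, y, p = 8)
  expect_equal(mean(sg$value), gc, tolerance = 0.1 * gc)
})

test_that("plug-in transfer entropy is exactly 1 bit on the balanced binary toy", {
  # de Bruijn-style drive makes the empirical joint exactly uniform
  xf <- rep(c(0, 0, 1, 1), 251)
  x <- xf[2:1002]; y <- xf[1:1001]        # y[n] = x[n-1], no padding
  expect_equal(te_plugin_discrete(x, y, m = 1, h = 1, l = 1), 1)
  # random coin: approaches 1 bit
  set.seed(11)
  xr <- sample(0:1, 4000, replace = TRUE)
  yr <- c(0, xr[-4000])
  expect_equal(te_plugin_discrete(xr, yr, m = 1, h = 1, l = 1), 1,
               tolerance = 0.01)
  # no influence: zero
  expect_lt(te_plugin_discrete(xr, sample(0:1, 4000, TRUE), m = 1, h = 1), 0.01)
})

test_that("kNN transfer entropy is directional and recovers the interaction delay", {
  set.seed(12)
  cp <- sim_coupled(1200, d = 4, sd = 0.3)
  te_fwd <- fc_transfer_entropy(cp$x, cp$y, l_set = 1:10)
  te_rev <- fc_transfer_entropy(cp$y, cp$x, l_set = 1:10)
  expect_gt(te_fwd$value, 3 * max(te_rev$value, 0.01))
  expect_equal(te_fwd$l, 4)
  # independent signals: near zero (within estimator bias)
  te_null <- fc_transfer_entropy(rnorm(1000), rnorm(1000), l_set = 1:5)
  expect_lt(te_null$value, 0.1)
  expect_error(fc_transfer_entropy(rnorm(120), rnorm(120)), "insufficient")
})

test_that("all-pairs driver averages trials and respects symmetry", {
  set.seed(13)
  M <- matrix(rnorm(4000), 1000, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  fc <- fc_estimate(list(M), "pearson")
  expect_true(isSymmetric(unname(fc$values)) ||
              all(abs(fc$values - t(fc$values)) < 1e-12, na.rm = TRUE))
  expect_true(all(is.na(diag(fc$values))))
  # identical trials average to the single-trial value
  fc3 <- fc_estimate(list(M, M, M), "pearson")
  expect_equal(fc3$values, fc$values)
  expect_equal(fc3$n_trials, 3)
  expect_error(fc_estimate(list(M), "no_such"), "arg")
})
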