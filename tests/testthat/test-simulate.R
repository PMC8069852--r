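test_that("simulation is a pure function of (config, seed)", {
  net <- iso_net("beta")
  s1 <- simulate(net, seed = 7, duration = 2)
  s2 <- simulate(net, seed = 7, duration = 2)
  expect_identical(s1$v_p, s2$v_p)
  s3 <- simulate(net, seed = 8, duration = 2)
  expect_false(identical(s1$v_p, s3$v_p))
  expect_identical(s1$config_hash, s3$config_hash)
})

test_that("autonomous network without input or noise settles to rest", {
  rois <- standard_rois(Ip = 0)
  net <- nmm_network(rois)
  s <- simulate(net, seed = 1, duration = 3, noise_scale = 0)
  tail_v <- s$v_p[s$t > 2.5, ]
  expect_true(all(apply(tail_v, 2, function(v) diff(range(v)) < 1e-6)))
})

test_that("noise enters through low-pass glutamatergic kinetics", {
  # quiescent region, noise only: spectrum on v_p must be low-pass shaped
  net <- iso_net("alpha", Ip = 0)
  s <- simulate(net, seed = 3)
  M <- preprocess(s)
  p <- psd_welch(M[, 1])
  p5 <- p$psd[which.min(abs(p$f - 5))]
  p40 <- p$psd[which.min(abs(p$f - 40))]
  expect_gt(p5, p40)
})

test_that("strong input saturates the firing rate and flattens the rhythm", {
  net400 <- iso_net("beta", Ip = 400)
  net2k <- iso_net("beta", Ip = 2000)
  s400 <- simulate(net400, seed = 2, duration = 5)
  s2k <- simulate(net2k, seed = 2, duration = 5)
  late <- s2k$t > 1
  expect_gt(mean(s2k$z_p[late, 1]), 4.9)       # near the upper asymptote 5
  expect_lt(sd(preprocess(s2k)[, 1]), 0.5 * sd(preprocess(s400)[, 1]))
})

test_that("preprocessing yields 1000 samples at 100 Hz and preserves DC", {
  net <- iso_net("theta")
  s <- simulate(net, seed = 1)
  M <- preprocess(s)
  expect_equal(nrow(M), 1000)
  expect_equal(attr(M, "fs"), 100)
  # constant signal passes unchanged (zero-phase, unit DC gain)
  const <- matrix(3.7, 20000, 1)
  out <- preprocess(const, dt = 1e-4)
  expect_equal(mean(out), 3.7, tolerance = 1e-4)
  expect_lt(diff(range(out)), 0.01)
  expect_error(preprocess(matrix(0, 100, 1), dt = 1e-4), "shorter")
})

test_that("antialiasing filter attenuates a 60 Hz tone by more than 20 dB", {
  dt <- 1e-4
  tt <- seq(0, 3, by = dt)
  x60 <- sin(2 * pi * 60 * tt)
  out <- preprocess(matrix(x60, ncol = 1), dt = dt)
  # residual 60 Hz aliases to 40 Hz at fs = 100; compare total power
  atten <- 10 * log10(var(as.numeric(out)) / var(x60))
  expect_lt(atten, -20)
})

test_that("Welch density integrates to the variance and localizes tones", {
  set.seed(5)
  x <- rnorm(1000)
  p <- psd_welch(x)
  expect_equal(sum(p$psd) * 0.1, var(x), tolerance = 0.15)
  expect_equal(p$f[2] - p$f[1], 0.1)
  tone <- sin(2 * pi * 10 * seq_len(1000) / 100)
  pt <- psd_welch(tone)
  expect_equal(pt$f[which.max(pt$psd)], 10, tolerance = 0.2)
  expect_error(psd_welch(rnorm(30)), "shorter")
})

test_that("band averaging is an inclusive arithmetic mean on the grid", {
  f <- seq(0, 50, by = 0.1)
  expect_equal(band_average(f, rep(3, length(f))), 3)
  expect_equal(band_average(f, f), 22)     # ramp over [4, 40]
  expect_error(band_average(f, f, band = c(60, 70)), "no grid")
})
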