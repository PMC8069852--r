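# Shared signal generators for estimator tests. All are seeded by the caller.

# bivariate VAR(1) simulator with known coefficient matrices
sim_var1 <- function(n, A, sd = c(1, 1), burn = 200) {
  X <- matrix(0, n + burn, 2)
  E <- cbind(rnorm(n + burn, sd = sd[1]), rnorm(n + burn, sd = sd[2]))
  for (t in 2:(n + burn)) X[t, ] <- A %*% X[t - 1, ] + E[t, ]
  X[(burn + 1):(burn + n), ]
}

# unidirectionally coupled pair: y[n] = a*y[n-1] + c*x[n-d] + noise
sim_coupled <- function(n, a = 0.5, c = 0.9, d = 1, sd = 0.5, burn = 200) {
  x <- as.numeric(stats::arima.sim(list(ar = 0.3), n + burn))
  y <- numeric(n + burn)
  e <- rnorm(n + burn, sd = sd)
  for (t in (d + 1):(n + burn)) y[t] <- a * y[t - 1] + c * x[t - d] + e[t]
  list(x = x[(burn + 1):(burn + n)], y = y[(burn + 1):(burn + n)])
}

# brute-force temporal Granger causality via two lm() regressions,
# independent of the package's qr-based implementation
gc_brute <- function(x, y, p) {
  x <- x - mean(x); y <- y - mean(y)
  n <- length(y)
  idx <- (p + 1):n
  lagm <- function(s) sapply(seq_len(p), function(k) s[idx - k])
  uni <- lm(y[idx] ~ lagm(y) - 1)
  biv <- lm(y[idx] ~ lagm(y) + lagm(x) - 1)
  log(mean(resid(uni)^2) / mean(resid(biv)^2))
}

# a small isolated one-region network
iso_net <- function(band, Ip = 400) {
  r <- roi_preset(band, Ip = Ip)
  nmm_network(setNames(list(r), band))
}
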