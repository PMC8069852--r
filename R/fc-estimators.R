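# Eight bivariate functional-connectivity estimators. All operate on a
# presynaptic signal x and a postsynaptic signal y sampled at fs (100 Hz
# after preprocessing); all demean internally. Directed estimators measure
# the influence x -> y.

.check_pair <- function(x, y) {
  if (length(x) != length(y)) stop("signals must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite input")
}

#' Pearson correlation between two signals
#'
#' Nondirected and signed: positive for excitatory-like, negative for
#' inhibitory-like covariation.
#'
#' @param x,y signal vectors of equal length.
#' @return correlation coefficient in \code{[-1, 1]}.
#' @export
fc_pearson <- function(x, y) {
  .check_pair(x, y)
  if (sd(x) == 0 || sd(y) == 0) stop("constant signal: correlation undefined")
  cor(x, y)
}

#' Delay-optimized correlation
#'
#' Correlates \code{x[n]} with the delayed \code{y[n + d]} and picks the
#' delay \code{d >= 0} that maximizes the absolute correlation (information
#' needs a finite time to travel from the presynaptic to the postsynaptic
#' region). The signed value at the optimum is returned together with the
#' delay; scoring against ground truth uses the absolute value, sign
#' analyses use the signed one.
#'
#' @param x presynaptic signal.
#' @param y postsynaptic signal.
#' @param max_delay largest delay searched, in samples (default 50, i.e.
#'   0.5 s at 100 Hz).
#' @return list with \code{value} (signed correlation at the optimum) and
#'   \code{delay} (samples).
#' @export
fc_delayed_correlation <- function(x, y, max_delay = 50) {
  .check_pair(x, y)
  n <- length(x)
  if (max_delay >= n / 2) stop("max_delay must be below half the length")
  vals <- vapply(0:max_delay, function(d) {
    xs <- x[seq_len(n - d)]
    ys <- y[seq_len(n - d) + d]
    if (sd(xs) == 0 || sd(ys) == 0) return(NA_real_)
    cor(xs, ys)
  }, 0)
  if (all(is.na(vals))) stop("constant signal: correlation undefined")
  d <- which.max(abs(vals)) - 1L
  list(value = vals[d + 1L], delay = d)
}

#' Magnitude-squared coherence profile
#'
#' \code{|Pyx|^2 / (Pxx Pyy)} from Welch auto- and cross-spectra
#' (0.5 s Hamming windows, 50\% overlap, zero padding to a 0.1 Hz grid).
#' Nondirected; 1 at every frequency for identical signals.
#'
#' @param x,y signal vectors.
#' @param fs sampling rate (Hz), default 100.
#' @return data.frame with columns \code{f} and \code{value} in [0, 1].
#' @export
fc_coherence <- function(x, y, fs = 100) {
  .check_pair(x, y)
  sp <- .welch_spectra(cbind(x, y), fs = fs)
  Pxx <- Re(sp$S[, 1, 1]); Pyy <- Re(sp$S[, 2, 2]); Pyx <- sp$S[, 2, 1]
  den <- Pxx * Pyy
  val <- ifelse(den > 0, Mod(Pyx)^2 / den, 0)
  data.frame(f = sp$f, value = pmin(pmax(val, 0), 1))
}

#' Lagged coherence profile
#'
#' Coherence variant built from the imaginary cross-spectrum only,
#' \code{Im(Pyx)^2 / (Pxx Pyy - Re(Pyx)^2)}: insensitive to instantaneous
#' (zero-lag) mixing, so \code{y = a x} gives values near zero.
#' Degenerate denominators yield 0 (with a warning).
#'
#' @inheritParams fc_coherence
#' @return data.frame with columns \code{f} and \code{value}.
#' @export
fc_lagged_coherence <- function(x, y, fs = 100) {
  .check_pair(x, y)
  sp <- .welch_spectra(cbind(x, y), fs = fs)
  Pxx <- Re(sp$S[, 1, 1]); Pyy <- Re(sp$S[, 2, 2]); Pyx <- sp$S[, 2, 1]
  den <- Pxx * Pyy - Re(Pyx)^2
  bad <- den <= 0
  if (any(bad)) warning("degenerate denominator at some frequencies; set to 0")
  val <- ifelse(bad, 0, Im(Pyx)^2 / den)
  data.frame(f = sp$f, value = pmin(pmax(val, 0), 1))
}

# analytic signal via FFT (Marple): zero negative frequencies
.analytic <- function(x) {
  x <- x - mean(x)
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Hilbert phase synchronization
#'
#' Modulus of the time-averaged unit phasor of the instantaneous phase
#' difference between the two analytic signals (phases from the Hilbert
#' transform of the demeaned signals). Transform edge transients are
#' removed by discarding \code{trim} seconds at each end before averaging.
#'
#' @inheritParams fc_coherence
#' @param trim seconds discarded at each end of the phase series
#'   (default 0.5).
#' @return scalar in [0, 1]; nondirected.
#' @export
fc_phase_sync <- function(x, y, fs = 100, trim = 0.5) {
  .check_pair(x, y)
  phx <- Arg(.analytic(x))
  phy <- Arg(.analytic(y))
  k <- round(trim * fs)
  n <- length(x)
  keep <- (k + 1):(n - k)
  Mod(mean(exp(1i * (phy[keep] - phx[keep]))))
}

# --- autoregressive machinery -----------------------------------------------

# lagged design matrix: columns x[n-1] ... x[n-p] aligned with x[(p+1):n]
.lag_design <- function(x, p, n) {
  sapply(seq_len(p), function(k) x[(p + 1 - k):(n - k)])
}

#' Fit univariate and bivariate autoregressive models of a signal pair
#'
#' Least-squares fits of (i) the univariate AR(p) model of each signal and
#' (ii) the joint bivariate VAR(p), on demeaned signals. Residual variances
#' use the maximum-likelihood divisor (number of fitted time points) so
#' that the nested-model inequality holds exactly in sample. When
#' \code{p = NULL} the order is selected by BIC of the joint model over
#' \code{orders}.
#'
#' @param x,y signal vectors.
#' @param p model order; \code{NULL} for BIC selection.
#' @param orders candidate orders for BIC selection (default 2:20).
#' @return object of class \code{ar_fit}: list with order \code{p},
#'   univariate coefficient matrix \code{a} (2 x p; rows x, y) and residual
#'   variances \code{gamma} (length 2), joint coefficient array \code{A}
#'   (2 x 2 x p, rows = equations for x, y), residual covariance
#'   \code{Sigma}, and the number of fitted points \code{n_eff}.
#' @export
fit_ar <- function(x, y, p = NULL, orders = 2:20) {
  .check_pair(x, y)
  x <- x - mean(x); y <- y - mean(y)
  n <- length(x)
  fit_joint <- function(p) {
    Z <- cbind(.lag_design(x, p, n), .lag_design(y, p, n))
    Yt <- cbind(x[(p + 1):n], y[(p + 1):n])
    qrZ <- qr(Z)
    if (qrZ$rank < ncol(Z)) stop("rank-deficient AR regressors")
    B <- qr.coef(qrZ, Yt)               # 2p x 2
    E <- Yt - Z %*% B
    Sigma <- crossprod(E) / nrow(E)
    list(B = B, Sigma = Sigma, n_eff = nrow(E))
  }
  if (is.null(p)) {
    bic <- vapply(orders, function(q) {
      f <- fit_joint(q)
      n_eff <- f$n_eff
      n_eff * log(det(f$Sigma)) + (4 * q) * log(n_eff)
    }, 0)
    p <- orders[which.min(bic)]
  }
  jf <- fit_joint(p)
  # univariate models, same estimation window for comparability
  uni <- function(s) {
    Z <- .lag_design(s, p, n)
    tgt <- s[(p + 1):n]
    cf <- qr.coef(qr(Z), tgt)
    e <- tgt - Z %*% cf
    list(coef = cf, gvar = sum(e^2) / length(e))
  }
  ux <- uni(x); uy <- uni(y)
  A <- array(0, dim = c(2, 2, p))
  # joint design columns: x lags 1..p then y lags 1..p; B columns: eq x, eq y
  for (k in seq_len(p)) {
    A[1, 1, k] <- jf$B[k, 1];     A[1, 2, k] <- jf$B[p + k, 1]
    A[2, 1, k] <- jf$B[k, 2];     A[2, 2, k] <- jf$B[p + k, 2]
  }
  structure(list(p = p,
                 a = rbind(x = ux$coef, y = uy$coef),
                 gamma = c(x = ux$gvar, y = uy$gvar),
                 A = A, Sigma = jf$Sigma, n_eff = jf$n_eff),
            class = "ar_fit")
}

#' Temporal Granger causality
#'
#' \code{GC_yx = ln(var(eta_y) / var(eps_y))}: the log ratio of the
#' univariate AR residual variance of the target over its residual variance
#' in the bivariate model that also uses the past of the source. In-sample
#' the ratio is >= 1, so the measure is nonnegative. Directed (x -> y).
#'
#' @param x presynaptic signal.
#' @param y postsynaptic signal.
#' @param p AR order, \code{NULL} for BIC selection (see
#'   \code{\link{fit_ar}}).
#' @param fit optional precomputed \code{ar_fit} of the pair.
#' @return scalar \code{GC_yx >= 0}.
#' @export
fc_granger_time <- function(x, y, p = NULL, fit = NULL) {
  if (is.null(fit)) fit <- fit_ar(x, y, p = p)
  g <- fit$gamma["y"]
  s <- fit$Sigma[2, 2]
  if (g <= 0 || s <= 0) stop("nonpositive residual variance")
  unname(log(g / s))
}

#' Spectral Granger causality profile
#'
#' Geweke's frequency decomposition from the joint bivariate VAR: with
#' transfer matrix \code{H(f) = A(f)^-1} and spectral matrix
#' \code{S(f) = H Sigma H*}, the causality from x to y at frequency f is
#' \code{ln(Syy / (Syy - (sxx - sxy^2/syy) |Hyx|^2))}, the log ratio of the
#' total power of y over its intrinsic (non-causal) part. The 4-40 Hz band
#' average supplies the scalar used for network scoring.
#'
#' @inheritParams fc_granger_time
#' @param fs sampling rate (Hz), default 100.
#' @param f frequency grid; default \code{seq(0, fs/2, by = 0.1)}.
#' @return data.frame with columns \code{f} and \code{value} (>= 0).
#' @export
fc_granger_spectral <- function(x, y, p = NULL, fit = NULL, fs = 100,
                                f = seq(0, fs / 2, by = 0.1)) {
  if (is.null(fit)) fit <- fit_ar(x, y, p = p)
  A <- fit$A; Sigma <- fit$Sigma; ord <- fit$p
  sxx <- Sigma[1, 1]; syy <- Sigma[2, 2]; sxy <- Sigma[1, 2]
  sxx_t <- sxx - sxy^2 / syy            # noise term normalized against y
  val <- vapply(f, function(fr) {
    zk <- exp(-2i * pi * fr * seq_len(ord) / fs)
    Af <- diag(2) + 0i
    for (k in seq_len(ord)) Af <- Af - A[, , k] * zk[k]
    H <- solve(Af)
    S <- H %*% Sigma %*% Conj(t(H))
    Syy <- Re(S[2, 2])
    den <- Syy - sxx_t * Mod(H[2, 1])^2
    if (den <= 0 || Syy <= 0) return(NA_real_)
    log(Syy / den)
  }, 0)
  # numerical guard: rare nonpositive denominators interpolated over
  if (anyNA(val)) {
    ok <- !is.na(val)
    if (sum(ok) < 2) stop("unstable AR fit: try a different order")
    val <- approx(f[ok], val[ok], xout = f, rule = 2)$y
  }
  data.frame(f = f, value = pmax(val, 0))
}

#' Transfer entropy (Kraskov estimator)
#'
#' Conditional mutual information \code{I(y[n]; X_past | Y_past)} in bits,
#' estimated with the Kraskov-style k-nearest-neighbour method on embedded
#' vectors: target past \code{Y_h(n - dn)} (h samples back at spacing dn)
#' and source past \code{X_m(n - l*dn)} shifted by the interaction delay
#' \code{l*dn}. The delay multiplier l is unknown a priori and is selected
#' by scanning \code{l_set} and keeping the maximizing value.
#'
#' @param x presynaptic signal.
#' @param y postsynaptic signal.
#' @param m,h embedding dimensions of source and target past (default 3).
#' @param dn embedding delay in samples (default 1).
#' @param l_set candidate interaction-delay multipliers (default 1:30).
#' @param k number of neighbours (default 4).
#' @return list with \code{value} (bits, max over \code{l_set}), \code{l}
#'   (the maximizing multiplier) and \code{profile} (TE per candidate).
#' @export
fc_transfer_entropy <- function(x, y, m = 3, h = 3, dn = 1, l_set = 1:30,
                                k = 4) {
  .check_pair(x, y)
  n <- length(x)
  if (n - (max(m, h) + max(l_set)) * dn < 100) {
    stop("insufficient samples for the chosen embedding")
  }
  x <- as.numeric(scale(x)); y <- as.numeric(scale(y))
  prof <- .te_ksg_scan(x, y, as.integer(m), as.integer(h), as.integer(dn),
                       as.integer(l_set), as.integer(k)) / log(2)
  i <- which.max(prof)
  list(value = prof[i], l = l_set[i], profile = setNames(prof, l_set))
}

#' Plug-in transfer entropy for discrete signals
#'
#' Exact evaluation of the transfer-entropy sum from empirical joint
#' probability tables; intended for small discrete toys where the
#' distribution can be enumerated (e.g. binary Markov constructions).
#'
#' @inheritParams fc_transfer_entropy
#' @param l interaction-delay multiplier (default 1).
#' @return transfer entropy in bits.
#' @export
te_plugin_discrete <- function(x, y, m = 1, h = 1, dn = 1, l = 1) {
  .check_pair(x, y)
  n <- length(x)
  start <- max(h * dn, (l + m - 1) * dn) + 1
  idx <- start:n
  key <- function(M) apply(M, 1, paste, collapse = "\r")
  Yp <- sapply(seq_len(h), function(j) y[idx - j * dn])
  Xp <- sapply(seq_len(m), function(j) x[idx - (l + j - 1) * dn])
  Yp <- matrix(Yp, ncol = h); Xp <- matrix(Xp, ncol = m)
  yv <- y[idx]
  kj  <- paste(yv, key(Yp), key(Xp))   # (y, Ypast, Xpast)
  kyp <- paste(yv, key(Yp))            # (y, Ypast)
  kzx <- paste(key(Yp), key(Xp))       # (Ypast, Xpast)
  kz  <- key(Yp)                       # (Ypast)
  N <- length(idx)
  pj <- table(kj) / N
  lookup <- function(tb, keys) as.numeric(tb[keys])
  tj <- table(kj); typ <- table(kyp); tzx <- table(kzx); tz <- table(kz)
  # sum over observed joint outcomes
  u <- !duplicated(kj)
  p_j <- lookup(tj, kj[u]) / N
  num <- lookup(tj, kj[u]) / lookup(tzx, kzx[u])   # p(y | Ypast, Xpast)
  den <- lookup(typ, kyp[u]) / lookup(tz, kz[u])   # p(y | Ypast)
  sum(p_j * log2(num / den))
}

# --- estimator registry and all-pairs driver --------------------------------

.fc_estimators <- c("pearson", "delayed_correlation", "coherence",
                    "lagged_coherence", "phase_sync", "granger_time",
                    "granger_spectral", "transfer_entropy")

.fc_directed <- c(pearson = FALSE, delayed_correlation = TRUE,
                  coherence = FALSE, lagged_coherence = FALSE,
                  phase_sync = FALSE, granger_time = TRUE,
                  granger_spectral = TRUE, transfer_entropy = TRUE)

#' Names of the available estimators
#' @return character vector of estimator names.
#' @export
fc_estimator_names <- function() .fc_estimators

#' Estimate a connectivity matrix from simulated trials
#'
#' Applies one estimator to every ordered region pair of each trial's
#' preprocessed pyramidal potentials and averages across trials.
#' Frequency-resolved estimators (coherence, lagged coherence, spectral
#' Granger) are reduced to scalars by their 4-40 Hz band average.
#' Nondirected estimators fill both (i, j) and (j, i); signed estimators
#' (correlation, delayed correlation) retain their sign — use
#' \code{abs()} when scoring against a binary structure.
#'
#' @param trials a single \code{nmm_sim}, a list of them, or a list of
#'   preprocessed matrices (time x region).
#' @param estimator one of \code{fc_estimator_names()}.
#' @param band band used to reduce spectral profiles, default c(4, 40).
#' @param ar_order fixed AR order for the Granger estimators (NULL = BIC).
#' @param te_l_set candidate interaction delays for transfer entropy.
#' @param fs analysis sampling rate (Hz).
#' @return object of class \code{fc_matrix}: the estimate matrix
#'   \code{[source, target]} with NA diagonal, plus estimator metadata.
#' @export
fc_estimate <- function(trials, estimator = "granger_time", band = c(4, 40),
                        ar_order = NULL, te_l_set = 1:30, fs = 100) {
  estimator <- match.arg(estimator, .fc_estimators)
  if (inherits(trials, "nmm_sim")) trials <- list(trials)
  mats <- lapply(trials, function(tr) {
    if (inherits(tr, "nmm_sim")) preprocess(tr) else as.matrix(tr)
  })
  nroi <- ncol(mats[[1]])
  nm <- colnames(mats[[1]])
  if (is.null(nm)) nm <- paste0("roi", seq_len(nroi))
  acc <- matrix(0, nroi, nroi, dimnames = list(nm, nm))
  for (M in mats) {
    est <- matrix(NA_real_, nroi, nroi)
    for (i in seq_len(nroi)) for (j in seq_len(nroi)) {
      if (i == j) next
      if (!.fc_directed[[estimator]] && i > j) next
      x <- M[, i]; y <- M[, j]
      v <- switch(estimator,
        pearson = fc_pearson(x, y),
        delayed_correlation = fc_delayed_correlation(x, y)$value,
        coherence = {
          pr <- fc_coherence(x, y, fs = fs)
          band_average(pr$f, pr$value, band)
        },
        lagged_coherence = {
          pr <- fc_lagged_coherence(x, y, fs = fs)
          band_average(pr$f, pr$value, band)
        },
        phase_sync = fc_phase_sync(x, y, fs = fs),
        granger_time = fc_granger_time(x, y, p = ar_order),
        granger_spectral = {
          pr <- fc_granger_spectral(x, y, p = ar_order, fs = fs)
          band_average(pr$f, pr$value, band)
        },
        transfer_entropy = fc_transfer_entropy(x, y, l_set = te_l_set)$value)
      est[i, j] <- v
      if (!.fc_directed[[estimator]]) est[j, i] <- v
    }
    acc <- acc + est
  }
  acc <- acc / length(mats)
  diag(acc) <- NA_real_
  structure(list(estimator = estimator, values = acc,
                 n_trials = length(mats), directed = .fc_directed[[estimator]]),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("<fc_matrix> %s (%s), %d trial%s averaged [source x target]\n",
              x$estimator, if (x$directed) "directed" else "nondirected",
              x$n_trials, if (x$n_trials > 1) "s" else ""))
  print(round(x$values, digits))
  invisible(x)
}
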