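# Simulation front end: forward-Euler integration of a network (compiled
# core), preprocessing to analysis-ready signals, and Welch spectra.

.config_hash <- function(net) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(net, f)
  unname(tools::md5sum(f))
}

#' Simulate a network of neural mass regions
#'
#' Integrates the full network with the Euler method. Gaussian white noise
#' enters the pyramidal input pathway \code{u_p} of every region, so it
#' reaches the membrane potential only through the low-pass glutamatergic
#' kinetics (the effective noise on \code{v_p} is 1/f-like, not white). The
#' per-step noise standard deviation is \code{5/sqrt(dt)}, the
#' Euler-Maruyama discretization of white noise with flat spectral density
#' 25; see the methods vignette. Long-range drive is the source region's
#' pyramidal spike density, weighted and then filtered by the target's
#' glutamatergic kinetics.
#'
#' @param object an \code{\link{nmm_network}}.
#' @param nsim number of noise trials. Trial \code{k} uses seed
#'   \code{seed + k - 1}, so different conditions run under identical noise
#'   streams.
#' @param seed integer base seed; identical seed gives bit-identical output.
#' @param duration simulated time (s), default 11.
#' @param dt Euler step (s), default 1e-4.
#' @param noise_scale multiplier on the standard noise level (0 disables
#'   noise; 1 is the study condition).
#' @param ... unused.
#' @return for \code{nsim = 1} an object of class \code{nmm_sim}: list with
#'   \code{t}, matrices \code{v_p} and \code{z_p} (time x region), and the
#'   \code{dt}, \code{seed} and \code{config_hash} provenance fields. For
#'   \code{nsim > 1}, a list of such objects.
#' @examples
#' net <- nmm_network(list(alpha = roi_preset("alpha")))
#' sim <- simulate(net, seed = 1, duration = 2)
#' @export
simulate.nmm_network <- function(object, nsim = 1, seed = 1, duration = 11,
                                 dt = 1e-4, noise_scale = 1, ...) {
  stopifnot(dt > 0, duration > 0, nsim >= 1)
  net <- object
  n <- length(net$rois)
  g <- function(fld) vapply(net$rois, `[[`, 0, fld)
  C <- vapply(net$rois, function(r) unname(r$C), numeric(8))
  C <- matrix(C, nrow = 8)
  hash <- .config_hash(net)
  nsteps <- round(duration / dt)
  one <- function(s) {
    set.seed(s)
    out <- .nmm_integrate(C, Ge = g("Ge"), we = g("we"),
                          Gs = g("Gs"), ws = g("ws"),
                          Gf = g("Gf"), wf = g("wf"),
                          e0 = g("e0"), r = g("r"), v0 = g("v0"),
                          Ip = g("Ip"), If = g("If"),
                          Wexc = net$W_exc, Winh = net$W_inh,
                          noise_sd = rep(noise_scale * 5 / sqrt(dt), n),
                          dt = dt, nsteps = nsteps, keep_every = 1L)
    colnames(out$v_p) <- colnames(out$z_p) <- names(net$rois)
    structure(list(t = seq(0, by = dt, length.out = nsteps),
                   v_p = out$v_p, z_p = out$z_p, dt = dt,
                   duration = duration, seed = s, config_hash = hash),
              class = "nmm_sim")
  }
  if (nsim == 1) one(seed) else lapply(seed + seq_len(nsim) - 1, one)
}

#' @export
print.nmm_sim <- function(x, ...) {
  cat(sprintf("<nmm_sim> %g s at dt = %g s, %d regions (%s), seed %d\n",
              x$duration, x$dt, ncol(x$v_p),
              paste(colnames(x$v_p), collapse = ", "), x$seed))
  invisible(x)
}

#' @export
plot.nmm_sim <- function(x, last = 1, ...) {
  n <- ncol(x$v_p)
  keep <- x$t >= max(x$t) - last
  op <- par(mfrow = c(n, 1), mar = c(2, 4, 1, 1))
  on.exit(par(op))
  for (j in seq_len(n)) {
    plot(x$t[keep], x$v_p[keep, j], type = "l", xlab = "",
         ylab = colnames(x$v_p)[j], ...)
  }
  invisible(x)
}

# zero-phase Butterworth low pass (applied forward and backward), with
# reflection padding so filter transients do not leak into the series ends
.zerophase_lp <- function(x, wc_norm, order = 6) {
  bt <- signal::butter(order, wc_norm)
  n <- length(x)
  pad <- min(n - 1, ceiling(6 / wc_norm))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filtfilt(bt, xp)
  y[(pad + 1):(pad + n)]
}

#' Preprocess a simulation for connectivity analysis
#'
#' Low-pass filters the pyramidal membrane potentials with a zero-phase
#' antialiasing filter (cut-off 50 Hz), resamples them at 100 Hz, and drops
#' the first second (initial transient). Decimation is performed in two
#' zero-phase Butterworth stages to keep the filters well conditioned.
#' The default 11 s simulation yields 1000 samples per region.
#'
#' @param sim an \code{nmm_sim} (or a plain matrix with sampling step
#'   \code{dt} given).
#' @param dt native sampling step, taken from \code{sim} when available.
#' @param fs_out output rate (Hz), default 100.
#' @param drop seconds dropped from the start, default 1.
#' @return matrix (time x region) of analysis-ready signals at
#'   \code{fs_out}, with attributes \code{fs} and \code{seed}.
#' @export
preprocess <- function(sim, dt = NULL, fs_out = 100, drop = 1) {
  if (inherits(sim, "nmm_sim")) {
    x <- sim$v_p
    dt <- sim$dt
    seed <- sim$seed
  } else {
    x <- as.matrix(sim)
    if (is.null(dt)) stop("dt required for plain matrices")
    seed <- NA_integer_
  }
  fs <- 1 / dt
  if (nrow(x) * dt <= drop) stop("simulation shorter than the dropped transient")
  dec_total <- fs / fs_out
  if (abs(dec_total - round(dec_total)) > 1e-8) {
    stop("native rate must be an integer multiple of fs_out")
  }
  dec_total <- round(dec_total)
  # split total decimation into stages of at most 10
  stages <- integer()
  rem <- dec_total
  while (rem > 1) {
    s <- min(10, rem)
    while (rem %% s != 0) s <- s - 1
    stages <- c(stages, s)
    rem <- rem / s
  }
  y <- x
  cur_fs <- fs
  for (s in stages) {
    target_ny <- cur_fs / s / 2
    wc <- if (cur_fs / s == fs_out) 50 / (cur_fs / 2) else 0.8 * target_ny / (cur_fs / 2)
    y <- apply(y, 2, .zerophase_lp, wc_norm = wc)
    y <- y[seq(1, nrow(y), by = s), , drop = FALSE]
    cur_fs <- cur_fs / s
  }
  y <- y[-seq_len(round(drop * fs_out)), , drop = FALSE]
  attr(y, "fs") <- fs_out
  attr(y, "seed") <- seed
  y
}

# --- Welch spectra -----------------------------------------------------------

# segment starts for a Welch estimate
.welch_frames <- function(n, win, overlap) {
  step <- max(1, round(win * (1 - overlap)))
  starts <- seq(1, n - win + 1, by = step)
  starts
}

# Welch auto/cross spectral matrix for a multichannel signal.
# Returns list(f, S) where S[f, i, j] = cross-spectral density of columns
# i and j, normalized so that sum(Re(S[, i, i])) * df == var(x[, i]) up to
# windowing loss compensation.
.welch_spectra <- function(x, fs, win = 0.5 * fs, nfft = 10 * fs,
                           overlap = 0.5) {
  x <- as.matrix(x)
  n <- nrow(x)
  win <- round(win)
  if (n < win) stop("signal shorter than one Welch window")
  x <- sweep(x, 2, colMeans(x))
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, win - 1) / (win - 1))  # Hamming
  starts <- .welch_frames(n, win, overlap)
  nc <- ncol(x)
  nf <- nfft %/% 2 + 1
  S <- array(0 + 0i, dim = c(nf, nc, nc))
  U <- sum(w^2)                       # window power
  for (s0 in starts) {
    seg <- x[s0:(s0 + win - 1), , drop = FALSE] * w
    segp <- rbind(seg, matrix(0, nfft - win, nc))  # zero padding
    X <- mvfft(segp)[seq_len(nf), , drop = FALSE]
    for (i in seq_len(nc)) for (j in seq_len(nc)) {
      S[, i, j] <- S[, i, j] + X[, i] * Conj(X[, j])
    }
  }
  S <- S / (length(starts) * U * fs)
  # one-sided: double everything except DC and Nyquist
  S[2:(nf - 1), , ] <- 2 * S[2:(nf - 1), , ]
  list(f = seq(0, fs / 2, length.out = nf), S = S)
}

#' Welch power spectral density
#'
#' Welch periodogram with a 0.5 s Hamming window, 50\% overlap and zero
#' padding to 10 s, giving a 0.1 Hz frequency grid at the 100 Hz analysis
#' rate. The density is normalized so that its integral equals the signal
#' variance.
#'
#' @param x numeric vector (one preprocessed signal).
#' @param fs sampling rate (Hz), default 100.
#' @param win window length in samples (default \code{0.5 * fs}).
#' @param nfft padded length (default \code{10 * fs}).
#' @param overlap fractional window overlap, default 0.5.
#' @return data.frame with columns \code{f} (Hz) and \code{psd}.
#' @export
psd_welch <- function(x, fs = 100, win = 0.5 * fs, nfft = 10 * fs,
                      overlap = 0.5) {
  sp <- .welch_spectra(matrix(as.numeric(x), ncol = 1), fs = fs, win = win,
                       nfft = nfft, overlap = overlap)
  data.frame(f = sp$f, psd = Re(sp$S[, 1, 1]))
}

#' Frequency of the spectral peak
#'
#' @param x signal vector.
#' @param fs sampling rate (Hz).
#' @param band frequency band searched, default 2-50 Hz.
#' @param ... passed to \code{\link{psd_welch}}.
#' @return peak frequency in Hz.
#' @export
peak_frequency <- function(x, fs = 100, band = c(2, 50), ...) {
  p <- psd_welch(x, fs = fs, ...)
  sel <- p$f >= band[1] & p$f <= band[2]
  p$f[sel][which.max(p$psd[sel])]
}

#' Average a spectral profile over a frequency band
#'
#' Arithmetic mean of the profile on the grid points inside the band
#' (inclusive); the 4-40 Hz default is the reduction used to turn
#' frequency-resolved connectivity profiles into scalars.
#'
#' @param f frequency grid (Hz).
#' @param value profile values on \code{f}.
#' @param band numeric c(lo, hi), default c(4, 40).
#' @return scalar band average.
#' @export
band_average <- function(f, value, band = c(4, 40)) {
  sel <- f >= band[1] & f <= band[2]
  if (!any(sel)) stop("band contains no grid points")
  mean(value[sel])
}
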