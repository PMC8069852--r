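# High-level experiments: the random-network estimator benchmark, the
# single-connection strength sweeps, the input (working point) sweeps and
# spectral connectivity reports. All are pure functions of their arguments
# and the base seed: trial k of every condition is simulated with seed
# base_seed + k - 1, so conditions differ only in the network, never in
# the noise stream.

.sim_trials <- function(net, n_trials, seed, duration, dt) {
  sims <- simulate(net, nsim = n_trials, seed = seed, duration = duration,
                   dt = dt)
  if (inherits(sims, "nmm_sim")) sims <- list(sims)
  lapply(sims, preprocess)
}

#' Random-network benchmark of the FC estimators
#'
#' Generates an ensemble of random four-region networks, simulates noise
#' trials of each, estimates connectivity with the requested estimators
#' (trial-averaged), and scores every estimator against the true binary
#' structure with pooled ROC / precision-recall curves and AUC.
#' Full-scale settings are 100 networks x 10 trials at dt = 1e-4; scaled
#' runs (e.g. 20 x 3 at dt = 2e-4) estimate the same AUC within sampling
#' error at a fraction of the cost.
#'
#' @param n_networks number of random networks.
#' @param n_trials noise trials per network.
#' @param duration,dt simulation length (s) and Euler step (s).
#' @param estimators character vector of estimator names (default all
#'   eight).
#' @param seed base seed: network sampling uses it as ensemble seed, trial
#'   k runs with seed + k - 1.
#' @param ar_order fixed AR order for Granger estimators (NULL = BIC).
#' @param te_l_set candidate transfer-entropy interaction delays.
#' @param verbose print progress.
#' @return object of class \code{fc_benchmark}: \code{auc} table,
#'   per-estimator \code{roc} objects, the \code{networks} and
#'   per-estimator \code{estimates}.
#' @export
run_benchmark <- function(n_networks = 100, n_trials = 10, duration = 11,
                          dt = 1e-4, estimators = fc_estimator_names(),
                          seed = 1, ar_order = NULL, te_l_set = 1:30,
                          verbose = FALSE) {
  estimators <- match.arg(estimators, .fc_estimators, several.ok = TRUE)
  nets <- random_networks(n = n_networks, seed = seed)
  est <- setNames(vector("list", length(estimators)), estimators)
  for (e in estimators) est[[e]] <- vector("list", n_networks)
  for (q in seq_len(n_networks)) {
    if (verbose) message(sprintf("network %d/%d", q, n_networks))
    mats <- .sim_trials(nets[[q]], n_trials, seed, duration, dt)
    for (e in estimators) {
      est[[e]][[q]] <- fc_estimate(mats, estimator = e, ar_order = ar_order,
                                   te_l_set = te_l_set)
    }
  }
  rocs <- lapply(est, fc_roc, truths = nets)
  auc <- data.frame(estimator = estimators,
                    auc = vapply(rocs, `[[`, 0, "auc"),
                    auc_rank = vapply(rocs, `[[`, 0, "auc_rank"),
                    row.names = NULL)
  auc <- auc[order(-auc$auc), ]
  structure(list(auc = auc, roc = rocs, networks = nets, estimates = est,
                 settings = list(n_networks = n_networks,
                                 n_trials = n_trials, duration = duration,
                                 dt = dt, seed = seed)),
            class = "fc_benchmark")
}

#' @export
print.fc_benchmark <- function(x, ...) {
  s <- x$settings
  cat(sprintf("<fc_benchmark> %d networks x %d trials (%g s, dt %g)\n",
              s$n_networks, s$n_trials, s$duration, s$dt))
  df <- x$auc
  df$auc <- sprintf("%.4f", df$auc)
  df$auc_rank <- sprintf("%.4f", df$auc_rank)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.fc_benchmark <- function(x, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  cols <- seq_along(x$roc)
  first <- TRUE
  for (i in cols) {
    cv <- x$roc[[i]]$curve
    if (which == "roc") {
      if (first) plot(cv$fpr, cv$tpr, type = "l", col = i,
                      xlab = "false positive rate",
                      ylab = "true positive rate", xlim = 0:1, ylim = 0:1,
                      ...)
      else lines(cv$fpr, cv$tpr, col = i)
    } else {
      if (first) plot(cv$recall, cv$precision, type = "l", col = i,
                      xlab = "recall", ylab = "precision", xlim = 0:1,
                      ylim = 0:1, ...)
      else lines(cv$recall, cv$precision, col = i)
    }
    first <- FALSE
  }
  if (which == "roc") abline(0, 1, lty = 3)
  legend("bottomright", legend = names(x$roc), col = cols, lty = 1,
         cex = 0.7, bty = "n")
  invisible(x)
}

#' Single-connection strength sweep experiment
#'
#' Varies one directed connection of the base network over a weight grid
#' (all else fixed), simulates trials at each grid point and estimates the
#' full connectivity matrix.
#'
#' @param source,target the swept directed connection (region names).
#' @param values weight grid, default \code{seq(0, 50, by = 10)}.
#' @param base base network, default the physiological preset.
#' @param estimator estimator name (default temporal Granger).
#' @param n_trials trials per grid point.
#' @param duration,dt simulation settings.
#' @param seed base seed.
#' @param ... passed to \code{\link{fc_estimate}}.
#' @return object of class \code{fc_sweep}: data.frame \code{curves} of the
#'   estimate of every ordered pair vs the swept value, plus the swept-pair
#'   summary from \code{\link{strength_response}}.
#' @export
run_sweep_strength <- function(source, target,
                               values = seq(0, 50, by = 10),
                               base = fig_network("physio"),
                               estimator = "granger_time", n_trials = 10,
                               duration = 11, dt = 1e-4, seed = 1, ...) {
  nets <- sweep_strength(source, target, values, base)
  res <- .run_condition_sweep(nets, values, estimator, n_trials, duration,
                              dt, seed, ...)
  swept <- res$curves[res$curves$source == source &
                      res$curves$target == target, ]
  sr <- strength_response(swept$value_swept, swept$estimate)
  structure(list(kind = "strength", source = source, target = target,
                 curves = res$curves, fc = res$fc, response = sr,
                 values = values),
            class = "fc_sweep")
}

#' Input (working point) sweep experiment
#'
#' Varies the external pyramidal input of one region over a grid, all else
#' fixed, estimating the full connectivity matrix at each level and the
#' thresholded graph at the 0.015 operating point.
#'
#' @param roi region whose input is swept.
#' @param values input grid (e.g. \code{seq(0, 800, by = 100)}).
#' @inheritParams run_sweep_strength
#' @param threshold detection threshold for the reported graphs.
#' @return object of class \code{fc_sweep} with per-level estimates and
#'   binarized graphs.
#' @export
run_sweep_input <- function(roi, values, base = fig_network("physio"),
                            estimator = "granger_time", n_trials = 10,
                            duration = 11, dt = 1e-4, seed = 1,
                            threshold = 0.015, ...) {
  nets <- sweep_input(roi, values, base)
  res <- .run_condition_sweep(nets, values, estimator, n_trials, duration,
                              dt, seed, ...)
  graphs <- lapply(res$fc, binarize_fc, threshold = threshold)
  structure(list(kind = "input", roi = roi, curves = res$curves,
                 fc = res$fc, graphs = graphs, values = values,
                 threshold = threshold),
            class = "fc_sweep")
}

.run_condition_sweep <- function(nets, values, estimator, n_trials,
                                 duration, dt, seed, ...) {
  fcs <- vector("list", length(nets))
  rows <- list()
  for (q in seq_along(nets)) {
    mats <- .sim_trials(nets[[q]], n_trials, seed, duration, dt)
    per_trial <- lapply(mats, function(M) {
      fc_estimate(list(M), estimator = estimator, ...)$values
    })
    avg <- Reduce(`+`, per_trial) / length(per_trial)
    fcs[[q]] <- structure(list(estimator = estimator, values = avg,
                               n_trials = length(per_trial),
                               directed = .fc_directed[[estimator]]),
                          class = "fc_matrix")
    nm <- rownames(avg)
    for (i in seq_along(nm)) for (j in seq_along(nm)) {
      if (i == j) next
      tv <- vapply(per_trial, function(v) v[i, j], 0)
      rows[[length(rows) + 1]] <- data.frame(
        value_swept = values[q], source = nm[i], target = nm[j],
        estimate = mean(tv), sd = if (length(tv) > 1) sd(tv) else NA_real_)
    }
  }
  names(fcs) <- values
  list(curves = do.call(rbind, rows), fc = fcs)
}

#' @export
print.fc_sweep <- function(x, ...) {
  if (x$kind == "strength") {
    cat(sprintf("<fc_sweep> strength %s -> %s over {%s}\n", x$source,
                x$target, paste(x$values, collapse = ", ")))
    cat(sprintf("  swept-pair Spearman rho = %.3f\n", x$response$spearman))
  } else {
    cat(sprintf("<fc_sweep> input to %s over {%s}\n", x$roi,
                paste(x$values, collapse = ", ")))
  }
  invisible(x)
}

#' Spectral connectivity report for a network
#'
#' Trial-averaged spectral Granger causality profiles for the requested
#' ordered region pairs.
#'
#' @param net an \code{nmm_network}.
#' @param pairs two-column character matrix (source, target); default all
#'   ordered pairs.
#' @param n_trials,duration,dt,seed simulation settings.
#' @param ar_order fixed AR order (NULL = BIC).
#' @return data.frame with columns source, target, f, value.
#' @export
spectral_report <- function(net, pairs = NULL, n_trials = 10, duration = 11,
                            dt = 1e-4, seed = 1, ar_order = NULL) {
  nm <- names(net$rois)
  if (is.null(pairs)) {
    pairs <- expand.grid(source = nm, target = nm,
                         stringsAsFactors = FALSE)
    pairs <- as.matrix(pairs[pairs$source != pairs$target, ])
  }
  mats <- .sim_trials(net, n_trials, seed, duration, dt)
  out <- list()
  for (q in seq_len(nrow(pairs))) {
    src <- pairs[q, 1]; tgt <- pairs[q, 2]
    prof <- NULL
    for (M in mats) {
      pr <- fc_granger_spectral(M[, src], M[, tgt], p = ar_order)
      prof <- if (is.null(prof)) pr$value else prof + pr$value
      f <- pr$f
    }
    out[[q]] <- data.frame(source = src, target = tgt, f = f,
                           value = prof / length(mats))
  }
  do.call(rbind, out)
}

#' Deterministic estimator test signals
#'
#' Builds the small synthetic signal pairs used to validate the estimators,
#' each with a known ground truth: a pure shift pair, a negated shift pair,
#' a unidirectional AR-coupled pair, the binary Markov transfer-entropy toy
#' (exactly 1 bit), and a signal-plus-independent-noise pair with coherence
#' 0.5 at the signal frequency.
#'
#' @param seed RNG seed.
#' @param n samples per signal (default 1000).
#' @return named list of toys; each has \code{x}, \code{y} and a
#'   \code{truth} description list.
#' @export
make_fixtures <- function(seed = 1, n = 1000) {
  set.seed(seed)
  shift_d <- 5
  x1 <- rnorm(n + shift_d)
  toys <- list()
  toys$shift <- list(x = x1[(shift_d + 1):(n + shift_d)],
                     y = x1[1:n],
                     truth = list(delay = shift_d, value = 1))
  toys$neg_shift <- list(x = x1[(3 + 1):(n + 3)], y = -x1[1:n],
                         truth = list(delay = 3, value = -1))
  # unidirectional AR coupling: y[n] = 0.5 y[n-1] + 0.9 x[n-1] + e
  x2 <- as.numeric(stats::arima.sim(list(ar = 0.3), n))
  y2 <- numeric(n)
  e <- rnorm(n, sd = 0.5)
  for (t in 2:n) y2[t] <- 0.5 * y2[t - 1] + 0.9 * x2[t - 1] + e[t]
  toys$ar_pair <- list(x = x2, y = y2, truth = list(direction = "x->y"))
  # binary Markov toy: y[n] = x[n-1], x iid fair coin -> TE exactly 1 bit
  xb <- sample(0:1, n, replace = TRUE)
  yb <- c(0, xb[-n])
  toys$te_binary <- list(x = xb, y = yb, truth = list(te_bits = 1))
  # coherence toy: y = x + independent noise with per-frequency SNR 1 in
  # the 8-12 Hz band of x -> expected coherence 0.5 there. Both series are
  # synthesized in the frequency domain with fixed amplitudes and random
  # phases so the spectral levels are exact by construction.
  rand_phase_signal <- function(amp) {
    half <- length(amp)
    ph <- runif(half, 0, 2 * pi)
    spec <- amp * exp(1i * ph)
    full <- c(0, spec, rev(Conj(spec[-half])))
    Re(fft(full, inverse = TRUE)) / n
  }
  fgrid <- seq_len(n / 2) * 100 / n
  amp_s <- ifelse(fgrid >= 8 & fgrid <= 12, 1, 0)
  s <- rand_phase_signal(amp_s)
  nz <- rand_phase_signal(ifelse(fgrid >= 8 & fgrid <= 12, 1, 0))
  toys$snr1 <- list(x = s, y = s + nz,
                    truth = list(coherence_in_band = 0.5,
                                 band = c(8, 12)))
  toys
}
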