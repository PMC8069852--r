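# Networks of regions. Long-range connections always originate from the
# pyramidal population of the source region; they either target pyramidal
# cells of the target region (excitatory, matrix W_exc) or its fast
# GABAergic interneurons (net inhibitory via the local f -> p synapse,
# "bisynaptic inhibition", matrix W_inh). Matrices are [source, target];
# a given ordered pair uses at most one of the two matrices.

#' Construct a network of neural mass regions
#'
#' @param rois list of \code{\link{roi_params}} (default the four standard
#'   rhythm presets theta, alpha, beta, gamma).
#' @param W_exc numeric matrix \code{[source, target]} of long-range weights
#'   onto pyramidal cells (monosynaptic excitation). Zero diagonal.
#' @param W_inh numeric matrix \code{[source, target]} of long-range weights
#'   onto fast interneurons (bisynaptic inhibition). Zero diagonal.
#' @param inputs optional numeric vector of external pyramidal inputs, one
#'   per region; overrides the \code{Ip} stored in each \code{roi_params}.
#' @return object of class \code{nmm_network}.
#' @examples
#' net <- nmm_network()            # four unconnected standard regions
#' net <- fig_network("physio")    # the physiological preset
#' @export
nmm_network <- function(rois = standard_rois(), W_exc = NULL, W_inh = NULL,
                        inputs = NULL) {
  n <- length(rois)
  stopifnot(n >= 1, all(vapply(rois, inherits, TRUE, "roi_params")))
  if (is.null(W_exc)) W_exc <- matrix(0, n, n)
  if (is.null(W_inh)) W_inh <- matrix(0, n, n)
  W_exc <- as.matrix(W_exc); W_inh <- as.matrix(W_inh)
  stopifnot(all(dim(W_exc) == n), all(dim(W_inh) == n))
  if (any(diag(W_exc) != 0) || any(diag(W_inh) != 0)) {
    stop("no self long-range connections: diagonals must be zero")
  }
  if (any(W_exc < 0) || any(W_inh < 0)) {
    stop("long-range weights must be nonnegative")
  }
  if (any(W_exc > 0 & W_inh > 0)) {
    stop("a directed pair is either excitatory or inhibitory, not both")
  }
  nm <- names(rois)
  if (is.null(nm)) nm <- vapply(rois, `[[`, "", "name")
  dimnames(W_exc) <- dimnames(W_inh) <- list(nm, nm)
  if (!is.null(inputs)) {
    stopifnot(length(inputs) == n)
    for (j in seq_len(n)) rois[[j]]$Ip <- unname(inputs[j])
  }
  structure(list(rois = setNames(rois, nm), W_exc = W_exc, W_inh = W_inh),
            class = "nmm_network")
}

#' @export
print.nmm_network <- function(x, ...) {
  n <- length(x$rois)
  cat(sprintf("<nmm_network> %d regions: %s\n", n,
              paste(names(x$rois), collapse = ", ")))
  cat("  inputs Ip:", paste(vapply(x$rois, `[[`, 0, "Ip"), collapse = ", "),
      "\n")
  el <- network_edges(x)
  if (nrow(el) == 0) {
    cat("  no long-range connections\n")
  } else {
    cat(sprintf("  %d long-range connections:\n", nrow(el)))
    for (i in seq_len(nrow(el))) {
      cat(sprintf("    %s -> %s  %g (%s)\n", el$source[i], el$target[i],
                  el$weight[i], el$sign[i]))
    }
  }
  invisible(x)
}

#' Edge list of a network
#'
#' @param net an \code{nmm_network}.
#' @return data.frame with columns source, target, weight, sign.
#' @export
network_edges <- function(net) {
  nm <- names(net$rois)
  out <- data.frame(source = character(), target = character(),
                    weight = numeric(), sign = character(),
                    stringsAsFactors = FALSE)
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (net$W_exc[i, j] > 0) {
      out <- rbind(out, data.frame(source = nm[i], target = nm[j],
                                   weight = net$W_exc[i, j],
                                   sign = "excitatory"))
    } else if (net$W_inh[i, j] > 0) {
      out <- rbind(out, data.frame(source = nm[i], target = nm[j],
                                   weight = net$W_inh[i, j],
                                   sign = "inhibitory"))
    }
  }
  out
}

#' True binary structure of a network
#'
#' @param net an \code{nmm_network}.
#' @return logical matrix \code{[source, target]}; TRUE where a long-range
#'   connection (of either sign) exists.
#' @export
ground_truth <- function(net) {
  (net$W_exc + net$W_inh) > 0
}

#' Preset connectivity networks
#'
#' \code{"physio"} is the physiologically inspired preset: the alpha region
#' (occipital/thalamic) inhibits the three others via bisynaptic connections,
#' the beta (motor) and gamma (fronto-temporal) regions excite each other,
#' and gamma and theta (hippocampal) excite each other; the alpha region
#' receives a reduced input (200), all others 400. \code{"loop"} is the
#' simple excitatory ring alpha -> beta -> gamma -> theta -> alpha with
#' input 400 everywhere. All preset weights are 20, the mid-range of the
#' random ensemble (transcribed defaults; see the methods vignette).
#'
#' @param which \code{"physio"} or \code{"loop"}.
#' @param weight common connection weight of the preset (default 20).
#' @return an \code{nmm_network}.
#' @export
fig_network <- function(which = c("physio", "loop"), weight = 20) {
  which <- match.arg(which)
  rois <- standard_rois()
  nm <- names(rois)
  We <- Wi <- matrix(0, 4, 4, dimnames = list(nm, nm))
  if (which == "physio") {
    Wi["alpha", "beta"]  <- weight
    Wi["alpha", "gamma"] <- weight
    Wi["alpha", "theta"] <- weight
    We["beta", "gamma"]  <- weight
    We["gamma", "beta"]  <- weight
    We["theta", "gamma"] <- weight
    We["gamma", "theta"] <- weight
    inputs <- c(theta = 400, alpha = 200, beta = 400, gamma = 400)
  } else {
    We["alpha", "beta"]  <- weight
    We["beta", "gamma"]  <- weight
    We["gamma", "theta"] <- weight
    We["theta", "alpha"] <- weight
    inputs <- c(theta = 400, alpha = 400, beta = 400, gamma = 400)
  }
  nmm_network(rois, W_exc = We, W_inh = Wi, inputs = inputs)
}

#' Sample one random network of the benchmark ensemble
#'
#' Draws the connectivity used by the random-network benchmark: the number
#' of directed long-range connections is uniform on \code{3:9}, the directed
#' pairs are drawn without replacement from the 12 ordered region pairs,
#' each weight is drawn uniformly from \code{{10, 20, 30, 40}}, and each
#' connection is excitatory or (bisynaptic) inhibitory with probability 1/2.
#' Every region receives the same external input.
#'
#' @param index network index (>= 1); together with \code{seed} it fully
#'   determines the draw.
#' @param seed ensemble seed.
#' @param n_range integer range of the connection count.
#' @param weights weight choices.
#' @param p_inh probability that a connection is inhibitory.
#' @param input common external input \code{Ip} (default 400).
#' @return an \code{nmm_network}.
#' @export
random_network <- function(index = 1, seed = 1, n_range = 3:9,
                           weights = c(10, 20, 30, 40), p_inh = 0.5,
                           input = 400) {
  stopifnot(index >= 1)
  # independent substream per (seed, index)
  set.seed(seed * 10000L + as.integer(index))
  rois <- standard_rois(Ip = input)
  nm <- names(rois)
  pairs <- which(!diag(4), arr.ind = TRUE)   # 12 ordered pairs
  k <- sample(n_range, 1)
  sel <- pairs[sample(nrow(pairs), k), , drop = FALSE]
  We <- Wi <- matrix(0, 4, 4, dimnames = list(nm, nm))
  for (q in seq_len(k)) {
    w <- sample(weights, 1)
    if (runif(1) < p_inh) {
      Wi[sel[q, 1], sel[q, 2]] <- w
    } else {
      We[sel[q, 1], sel[q, 2]] <- w
    }
  }
  nmm_network(rois, W_exc = We, W_inh = Wi)
}

#' The random-network ensemble
#'
#' @param n number of networks (100 at full scale).
#' @param seed ensemble seed.
#' @param ... passed to \code{\link{random_network}}.
#' @return list of \code{nmm_network}.
#' @export
random_networks <- function(n = 100, seed = 1, ...) {
  lapply(seq_len(n), random_network, seed = seed, ...)
}

#' Single-connection strength sweep
#'
#' Returns one network per grid value, identical to \code{base} except for
#' the weight of the given directed connection (its sign class is preserved;
#' a connection absent from the base is swept as excitatory).
#'
#' @param source,target region names of the directed connection.
#' @param values weight grid (default 0 to 50, step 10).
#' @param base base network (default the physiological preset).
#' @return named list of \code{nmm_network}, one per grid value.
#' @export
sweep_strength <- function(source, target, values = seq(0, 50, by = 10),
                           base = fig_network("physio")) {
  stopifnot(length(values) >= 1, !is.unsorted(values))
  inhib <- base$W_inh[source, target] > 0
  lapply(setNames(values, values), function(w) {
    net <- base
    if (inhib) net$W_inh[source, target] <- w else net$W_exc[source, target] <- w
    net
  })
}

#' Single-region input sweep
#'
#' Returns one network per grid value, identical to \code{base} except for
#' the external pyramidal input of one region.
#'
#' @param roi region name whose input is varied.
#' @param values input grid (e.g. \code{seq(0, 800, by = 100)}).
#' @param base base network (default the physiological preset).
#' @return named list of \code{nmm_network}.
#' @export
sweep_input <- function(roi, values, base = fig_network("physio")) {
  stopifnot(length(values) >= 1, !is.unsorted(values))
  lapply(setNames(values, values), function(I) {
    net <- base
    net$rois[[roi]]$Ip <- I
    net
  })
}
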