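# Plain-text serialization: YAML network configurations and CSV exports
# of simulations and connectivity matrices.

#' Write a network configuration to YAML
#'
#' Serializes the region parameters, both long-range weight structures (as
#' labeled edge lists) and the per-region inputs. The file round-trips
#' through \code{\link{read_network_yaml}}.
#'
#' @param net an \code{\link{nmm_network}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_network_yaml <- function(net, path) {
  rois <- lapply(net$rois, function(r) {
    list(name = r$name, Ge = r$Ge, we = r$we, Gs = r$Gs, ws = r$ws,
         Gf = r$Gf, wf = r$wf, e0 = r$e0, r = r$r, v0 = r$v0,
         C = as.list(r$C), Ip = r$Ip, If = r$If)
  })
  edges <- network_edges(net)
  obj <- list(
    rois = rois,
    connections = if (nrow(edges) == 0) list() else
      lapply(seq_len(nrow(edges)), function(i) {
        list(source = edges$source[i], target = edges$target[i],
             weight = edges$weight[i], sign = edges$sign[i])
      })
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a network configuration from YAML
#'
#' @param path file written by \code{\link{write_network_yaml}} (or
#'   hand-authored in the same schema).
#' @return an \code{\link{nmm_network}}.
#' @export
read_network_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  rois <- lapply(obj$rois, function(r) {
    roi_params(name = r$name, Ge = r$Ge, we = r$we, Gs = r$Gs, ws = r$ws,
               Gf = r$Gf, wf = r$wf, e0 = r$e0, r = r$r, v0 = r$v0,
               C = unlist(r$C), Ip = r$Ip, If = r$If)
  })
  names(rois) <- vapply(rois, `[[`, "", "name")
  n <- length(rois)
  We <- Wi <- matrix(0, n, n, dimnames = list(names(rois), names(rois)))
  for (cn in obj$connections) {
    if (identical(cn$sign, "inhibitory")) {
      Wi[cn$source, cn$target] <- cn$weight
    } else {
      We[cn$source, cn$target] <- cn$weight
    }
  }
  nmm_network(rois, W_exc = We, W_inh = Wi)
}

#' Export a simulation to CSV
#'
#' Writes columns \code{t}, \code{v_p_<region>} and \code{z_p_<region>};
#' the seed and configuration hash are recorded in comment lines at the
#' top of the file.
#'
#' @param sim an \code{nmm_sim}.
#' @param path output file path.
#' @param every keep every n-th sample (default 1, the native step).
#' @return \code{path}, invisibly.
#' @export
write_sim_csv <- function(sim, path, every = 1) {
  stopifnot(inherits(sim, "nmm_sim"))
  keep <- seq(1, length(sim$t), by = every)
  df <- data.frame(t = sim$t[keep], sim$v_p[keep, , drop = FALSE],
                   sim$z_p[keep, , drop = FALSE])
  names(df) <- c("t", paste0("v_p_", colnames(sim$v_p)),
                 paste0("z_p_", colnames(sim$z_p)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# seed: %d", sim$seed),
               sprintf("# config_hash: %s", sim$config_hash),
               sprintf("# dt: %g", sim$dt * every)), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Connectivity matrix as a tidy data frame
#'
#' @param x an \code{fc_matrix}.
#' @param ... unused.
#' @return data.frame with columns source, target, estimator, value,
#'   n_trials (diagonal omitted).
#' @export
as.data.frame.fc_matrix <- function(x, ...) {
  nm <- rownames(x$values)
  idx <- which(!diag(length(nm)), arr.ind = TRUE)
  data.frame(source = nm[idx[, 1]], target = nm[idx[, 2]],
             estimator = x$estimator, value = x$values[idx],
             n_trials = x$n_trials)
}
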