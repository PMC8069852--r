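# Scoring estimated connectivity against the true structure: pooled
# ROC / precision-recall curves, AUC, thresholded graphs and sweep
# summaries.

.pool_scores <- function(estimates, truths) {
  if (length(estimates) != length(truths)) {
    stop("one estimate per network required")
  }
  score <- truth <- NULL
  for (q in seq_along(estimates)) {
    v <- estimates[[q]]
    if (inherits(v, "fc_matrix")) v <- v$values
    tr <- truths[[q]]
    if (inherits(tr, "nmm_network")) tr <- ground_truth(tr)
    off <- !diag(nrow(v))
    score <- c(score, abs(v[off]))
    truth <- c(truth, tr[off])
  }
  list(score = score, truth = as.logical(truth))
}

#' Pooled ROC, precision-recall and AUC for one estimator
#'
#' Pools every ordered region pair across networks; a pair is predicted
#' present when its absolute estimate reaches the threshold. The ROC is
#' reported on the threshold grid (default 101 points on [0, 0.5]); the
#' trapezoidal AUC integrates the complete curve (grid extended beyond the
#' largest score so the curve reaches the origin), and the rank-based
#' (Mann-Whitney) AUC is reported alongside as a grid-free cross-check.
#'
#' @param estimates list of \code{fc_matrix} (or plain matrices), one per
#'   network.
#' @param truths list of \code{nmm_network} or logical matrices, matching
#'   \code{estimates}.
#' @param thresholds reported threshold grid, default
#'   \code{seq(0, 0.5, length.out = 101)}.
#' @return object of class \code{fc_roc}: data.frame \code{curve} with
#'   threshold, tp/fp/fn/tn counts, tpr, fpr, precision, recall;
#'   \code{auc} (trapezoidal) and \code{auc_rank}.
#' @export
fc_roc <- function(estimates, truths,
                   thresholds = seq(0, 0.5, length.out = 101)) {
  ps <- .pool_scores(estimates, truths)
  score <- ps$score; truth <- ps$truth
  npos <- sum(truth); nneg <- sum(!truth)
  if (npos == 0 || nneg == 0) stop("need both present and absent connections")
  conf <- function(thr) {
    pred <- score >= thr
    c(tp = sum(pred & truth), fp = sum(pred & !truth),
      fn = sum(!pred & truth), tn = sum(!pred & !truth))
  }
  curve <- t(vapply(thresholds, conf, numeric(4)))
  curve <- data.frame(threshold = thresholds, curve)
  curve$tpr <- curve$tp / npos
  curve$fpr <- curve$fp / nneg
  curve$precision <- ifelse(curve$tp + curve$fp > 0,
                            curve$tp / (curve$tp + curve$fp), 1)
  curve$recall <- curve$tpr
  # complete curve for integration: all distinct scores as thresholds
  thr_all <- sort(unique(c(0, score, max(score) + 1)))
  cc <- t(vapply(thr_all, conf, numeric(4)))
  fpr <- cc[, "fp"] / nneg
  tpr <- cc[, "tp"] / npos
  ordr <- order(fpr, tpr)
  fpr <- c(0, fpr[ordr], 1); tpr <- c(0, tpr[ordr], 1)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  # rank (Mann-Whitney) AUC with tie correction
  rk <- rank(score)
  auc_rank <- (sum(rk[truth]) - npos * (npos + 1) / 2) / (npos * nneg)
  structure(list(curve = curve, auc = auc, auc_rank = auc_rank,
                 n_pos = npos, n_neg = nneg),
            class = "fc_roc")
}

#' @export
print.fc_roc <- function(x, ...) {
  cat(sprintf("<fc_roc> %d true / %d absent pooled connections\n",
              x$n_pos, x$n_neg))
  cat(sprintf("  AUC %.4f (trapezoidal)  %.4f (rank)\n", x$auc, x$auc_rank))
  invisible(x)
}

#' Precision at a recall operating point
#'
#' Reads the precision at the threshold whose recall is closest to the
#' requested level from above.
#'
#' @param roc an \code{fc_roc}.
#' @param recall target recall (default 0.8).
#' @return precision (fraction in [0, 1]) at that operating point.
#' @export
precision_at_recall <- function(roc, recall = 0.8) {
  cv <- roc$curve
  ok <- cv$recall >= recall
  if (!any(ok)) return(NA_real_)
  cv <- cv[ok, ]
  cv$precision[which.min(cv$recall - recall)]
}

#' Threshold a connectivity matrix into a directed graph
#'
#' An edge is declared present when the absolute estimate reaches the
#' threshold (default 0.015, the operating point read from the benchmark
#' ROC).
#'
#' @param fc an \code{fc_matrix} or plain matrix.
#' @param threshold detection threshold (>= 0).
#' @return logical adjacency matrix \code{[source, target]}.
#' @export
binarize_fc <- function(fc, threshold = 0.015) {
  stopifnot(threshold >= 0)
  v <- if (inherits(fc, "fc_matrix")) fc$values else as.matrix(fc)
  adj <- !is.na(v) & abs(v) >= threshold & abs(v) > 0
  diag(adj) <- FALSE
  adj
}

#' Summarize estimates against true connection strengths
#'
#' For sweep or ensemble results: groups the estimated values of one
#' directed connection by its true weight and reports mean, SD and the
#' Spearman rank correlation between true weight and estimate.
#'
#' @param weights numeric vector of true weights.
#' @param estimates numeric vector of estimated values (same length).
#' @return list with \code{table} (weight, mean, sd, n) and \code{spearman}.
#' @export
strength_response <- function(weights, estimates) {
  stopifnot(length(weights) == length(estimates))
  u <- sort(unique(weights))
  tab <- data.frame(weight = u,
                    mean = vapply(u, function(w) mean(estimates[weights == w]), 0),
                    sd = vapply(u, function(w) sd(estimates[weights == w]), 0),
                    n = vapply(u, function(w) sum(weights == w), 0L))
  rho <- if (sd(estimates) == 0 || sd(weights) == 0) 0 else
    suppressWarnings(cor(weights, estimates, method = "spearman"))
  list(table = tab, spearman = rho)
}
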