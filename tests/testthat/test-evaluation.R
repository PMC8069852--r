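test_that("ROC scoring hits the textbook extremes", {
  nm <- c("theta", "alpha", "beta", "gamma")
  truth <- matrix(FALSE, 4, 4, dimnames = list(nm, nm))
  truth[1, 2] <- truth[2, 3] <- truth[3, 4] <- truth[4, 1] <- TRUE
  # perfectly separating scores
  est <- matrix(0.01, 4, 4); est[truth] <- 0.4; diag(est) <- NA
  roc <- fc_roc(list(est), list(truth))
  expect_equal(roc$auc, 1)
  expect_equal(roc$auc_rank, 1)
  # scores independent of truth, many networks -> AUC ~ 0.5
  set.seed(20)
  ests <- truths <- list()
  for (q in 1:40) {
    tr <- matrix(FALSE, 4, 4)
    tr[sample(which(!diag(4)), 5)] <- TRUE
    e <- matrix(abs(rnorm(16, 0.1, 0.05)), 4, 4); diag(e) <- NA
    truths[[q]] <- tr; ests[[q]] <- e
  }
  roc0 <- fc_roc(ests, truths)
  expect_equal(roc0$auc, 0.5, tolerance = 0.08)
  expect_error(fc_roc(ests[1:2], truths[1:3]), "one estimate per network")
})

test_that("trapezoidal and rank AUC agree and match an independent ROC oracle", {
  skip_if_not_installed("pROC")
  set.seed(21)
  ests <- truths <- list()
  for (q in 1:25) {
    tr <- matrix(FALSE, 4, 4)
    tr[sample(which(!diag(4)), 6)] <- TRUE
    e <- matrix(abs(rnorm(16, 0.05, 0.03)), 4, 4)
    e[tr] <- e[tr] + abs(rnorm(sum(tr), 0.08, 0.05))
    diag(e) <- NA
    truths[[q]] <- tr; ests[[q]] <- e
  }
  roc <- fc_roc(ests, truths)
  expect_equal(roc$auc, roc$auc_rank, tolerance = 0.02)
  # oracle: pROC on the pooled scores
  sc <- unlist(lapply(ests, function(e) e[!diag(4)]))
  tr <- unlist(lapply(truths, function(t) t[!diag(4)]))
  oracle <- suppressMessages(as.numeric(pROC::auc(tr, sc)))
  expect_equal(roc$auc_rank, oracle, tolerance = 1e-10)
})

test_that("precision is read at the recall operating point from above", {
  nm <- c("a", "b")
  curve <- data.frame(threshold = c(0, 0.1, 0.2),
                      recall = c(1, 0.85, 0.6),
                      precision = c(0.5, 0.7, 0.9))
  roc <- structure(list(curve = curve), class = "fc_roc")
  expect_equal(precision_at_recall(roc, 0.8), 0.7)
  expect_true(is.na(precision_at_recall(roc, 1.1)))
})

test_that("thresholding produces the documented graphs", {
  v <- matrix(0, 3, 3)
  expect_equal(sum(binarize_fc(v, 0.015)), 0)
  v[1, 2] <- 0.3; v[2, 1] <- -0.2; v[3, 1] <- 0.001
  g0 <- binarize_fc(v, 0)
  expect_equal(sum(g0), 3)             # every nonzero off-diagonal entry
  g <- binarize_fc(v, 0.015)
  expect_true(g[1, 2] && g[2, 1])      # absolute value is scored
  expect_false(g[3, 1])
  expect_error(binarize_fc(v, -1))
})

test_that("strength summaries report mean, SD and rank correlation", {
  w <- rep(c(0, 10, 20, 30), each = 3)
  est <- 0.01 * w
  sr <- strength_response(w, est)
  expect_equal(sr$spearman, 1)
  est <- est + 0.001 * rep(c(-1, 0, 1), 4)
  expect_equal(sr$table$weight, c(0, 10, 20, 30))
  expect_equal(sr$table$n, rep(3L, 4))
  cst <- strength_response(w, rep(2, 12))
  expect_equal(cst$spearman, 0)
  expect_equal(cst$table$sd, rep(0, 4))
  expect_equal(strength_response(w, est)$table$sd[1], sd(est[w == 0]))
})
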