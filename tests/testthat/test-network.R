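test_that("network construction enforces structural invariants", {
  expect_error(nmm_network(W_exc = diag(4)), "diagonal")
  W <- matrix(0, 4, 4); W[1, 2] <- 10
  expect_error(nmm_network(W_exc = W, W_inh = W), "either excitatory or")
  W2 <- matrix(0, 4, 4); W2[1, 2] <- -3
  expect_error(nmm_network(W_exc = W2), "nonnegative")
  net <- nmm_network(W_exc = W, inputs = c(100, 200, 300, 400))
  expect_equal(vapply(net$rois, `[[`, 0, "Ip"),
               c(theta = 100, alpha = 200, beta = 300, gamma = 400))
})

test_that("physiological preset has exactly the seven documented connections", {
  net <- fig_network("physio")
  el <- network_edges(net)
  got <- paste(el$source, el$target)
  want <- c("alpha beta", "alpha gamma", "alpha theta", "beta gamma",
            "gamma beta", "gamma theta", "theta gamma")
  expect_setequal(got, want)
  # the alpha links are inhibitory, the rest excitatory
  expect_true(all(el$sign[el$source == "alpha"] == "inhibitory"))
  expect_true(all(el$sign[el$source != "alpha"] == "excitatory"))
  expect_false(any(net$W_exc > 0 & net$W_inh > 0))
  expect_equal(net$rois$alpha$Ip, 200)
  expect_equal(net$rois$beta$Ip, 400)
  # absent pairs are truly absent
  tr <- ground_truth(net)
  expect_false(tr["beta", "theta"] || tr["theta", "beta"] ||
               tr["beta", "alpha"] || tr["gamma", "alpha"] ||
               tr["theta", "alpha"])
  # loop preset is a single ring
  lp <- ground_truth(fig_network("loop"))
  expect_equal(sum(lp), 4)
})

test_that("random ensemble respects the sampling protocol", {
  nets <- random_networks(n = 100, seed = 42)
  counts <- vapply(nets, function(n) sum(ground_truth(n)), 0L)
  expect_true(all(counts >= 3 & counts <= 9))
  ws <- unlist(lapply(nets, function(n) {
    w <- n$W_exc + n$W_inh
    w[w > 0]
  }))
  expect_true(all(ws %in% c(10, 20, 30, 40)))
  # excitatory fraction ~ Binomial(total, 0.5): check 99% interval
  n_exc <- sum(vapply(nets, function(n) sum(n$W_exc > 0), 0L))
  total <- sum(counts)
  expect_gt(n_exc / total, 0.5 - 2.6 * sqrt(0.25 / total))
  expect_lt(n_exc / total, 0.5 + 2.6 * sqrt(0.25 / total))
  # all inputs at the benchmark level
  expect_true(all(vapply(nets, function(n) all(vapply(n$rois, `[[`, 0, "Ip") == 400), TRUE)))
  # reproducible and index-sensitive
  expect_identical(random_network(7, seed = 42), random_network(7, seed = 42))
  expect_false(identical(random_network(7, seed = 42),
                         random_network(8, seed = 42)))
})

test_that("sweep generators vary exactly one quantity", {
  base <- fig_network("physio")
  sw <- sweep_strength("beta", "gamma", base = base)
  expect_length(sw, 6)
  expect_equal(vapply(sw, function(n) n$W_exc["beta", "gamma"], 0),
               setNames(seq(0, 50, 10), seq(0, 50, 10)))
  # all other entries untouched
  for (net in sw) {
    tmp <- net; tmp$W_exc["beta", "gamma"] <- base$W_exc["beta", "gamma"]
    expect_identical(tmp, base)
  }
  # weight 0 equals edge deletion
  del <- base; del$W_exc["beta", "gamma"] <- 0
  expect_identical(sw[["0"]], del)
  swi <- sweep_input("beta", c(0, 400, 800), base = base)
  ip <- vapply(swi, function(n) n$rois$beta$Ip, 0)
  expect_equal(unname(ip), c(0, 400, 800))
  expect_identical(swi[["400"]], base)
})
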