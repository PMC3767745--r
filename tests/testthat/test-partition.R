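## small cohort of per-subject networks with controlled edge trajectories
make_nets <- function(W_list, labels) {
  lapply(W_list, function(w) {
    dimnames(w) <- list(labels, labels)
    coherence_network(w, labels, 12.5)
  })
}

test_that("edges proportional to SNR are perfectly positively classified", {
  labels <- letters[1:4]
  snr <- c(1, 2, 3, 4, 5)
  nets <- make_nets(lapply(snr, function(s) {
    w <- matrix(0, 4, 4)
    w[1, 2] <- w[2, 1] <- 0.1 * s          # exactly proportional
    w[3, 4] <- w[4, 3] <- 0.9 - 0.1 * s    # exactly anti-proportional
    w[1, 3] <- w[3, 1] <- 0.5              # constant -> degenerate
    w
  }), labels)
  expect_warning(corr <- edgewise_correlation(nets, snr), "zero variance")
  part <- classify_edges(corr, alpha = 0.05)
  cls <- setNames(part$edges$class, paste(part$edges$node_i, part$edges$node_j))
  expect_identical(cls[["a b"]], "positive")
  expect_identical(cls[["c d"]], "negative")
  expect_identical(cls[["a c"]], "nonsig")
  expect_true(part$edges$degenerate[part$edges$node_i == "a" &
                                      part$edges$node_j == "c"])
  ab <- part$edges[part$edges$node_i == "a" & part$edges$node_j == "b", ]
  expect_equal(ab$r, 1, tolerance = 1e-12)
  expect_lt(ab$p, 1e-8)
})

test_that("classification respects the significance level and sign", {
  skel <- data.frame(node_i = c("a", "a", "b"), node_j = c("b", "c", "c"),
                     r = c(0.9, -0.7, 0.4), p = c(0.001, 0.03, 0.3),
                     n = 11, degenerate = FALSE, stringsAsFactors = FALSE)
  corr <- structure(skel, labels = c("a", "b", "c"),
                    class = c("edge_correlation", "data.frame"))
  part <- classify_edges(corr, alpha = 0.05)
  expect_identical(part$edges$class, c("positive", "negative", "nonsig"))
  strict <- classify_edges(corr, alpha = 0.01)
  expect_identical(strict$edges$class, c("positive", "nonsig", "nonsig"))
  expect_error(classify_edges(corr, alpha = 0), "alpha")
})

test_that("class sub-networks partition Network 0 and conserve weight", {
  set.seed(30)
  labels <- paste0("ch", 1:6)
  snr <- runif(6, 1, 5)
  nets <- make_nets(replicate(6, rand_connected_graph(6), simplify = FALSE),
                    labels)
  corr <- edgewise_correlation(nets, snr)
  part <- classify_edges(corr)
  for (s in seq_along(nets)) {
    n1 <- subnetwork(nets[[s]], part, "positive")
    n2 <- subnetwork(nets[[s]], part, "nonsig")
    n3 <- subnetwork(nets[[s]], part, "negative")
    expect_equal(n1$weights + n2$weights + n3$weights, nets[[s]]$weights)
    overlap <- (n1$weights > 0) & (n2$weights > 0)
    expect_false(any(overlap))
  }
  relabeled <- coherence_network(nets[[1]]$weights, rev(labels), 12.5)
  expect_error(subnetwork(relabeled, part, "positive"), "label mismatch")
})

test_that("subjects lacking a pruned edge contribute zero weight", {
  labels <- letters[1:3]
  w_full <- matrix(0, 3, 3)
  w_full[1, 2] <- w_full[2, 1] <- 0.8
  w_full[1, 3] <- w_full[3, 1] <- 0.4
  w_miss <- matrix(0, 3, 3)
  w_miss[1, 2] <- w_miss[2, 1] <- 0.2 # edge a-c absent for these subjects
  nets <- make_nets(list(w_full, w_miss, w_full, w_miss, w_full), labels)
  snr <- c(5, 1, 4.5, 1.2, 4)
  corr <- edgewise_correlation(nets, snr)
  ac <- corr[corr$node_i == "a" & corr$node_j == "c", ]
  ## oracle: zero-filled weights against the SNR vector
  want <- cor.test(c(0.4, 0, 0.4, 0, 0.4), snr)
  expect_equal(ac$r, unname(want$estimate), tolerance = 1e-12)
  expect_equal(ac$p, want$p.value, tolerance = 1e-12)
  ## b-c is absent in every subject: not part of the edge universe
  expect_false(any(corr$node_i == "b" & corr$node_j == "c"))
})

test_that("edgewise correlation validates its inputs", {
  labels <- letters[1:3]
  nets <- make_nets(list(rand_graph(3), rand_graph(3)), labels)
  expect_error(edgewise_correlation(nets, c(1, 2, 3)), "one entry per subject")
  expect_error(edgewise_correlation(nets, c(1, 2)), "at least 3 subjects")
})
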