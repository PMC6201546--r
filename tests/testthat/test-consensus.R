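edge_df <- function(n1, n2, w, p = 0.001) {
  data.frame(Node.1 = n1, Node.2 = n2, wTO_sign = w, pval_sig = p,
             stringsAsFactors = FALSE)
}

test_that("consensus weights follow the magnitude-weighted convex combination", {
  expect_equal(consensus_weights(c(0.5, 0.5))$omega, 0.5)
  expect_equal(consensus_weights(c(0.6, -0.6))$omega, 0)
  cw <- consensus_weights(c(0.8, 0.2))
  expect_equal(cw$alpha[1, ], c(0.8, 0.2))
  expect_equal(cw$omega, 0.68)
  # all-zero link: omega 0, contributions reported as zeros
  cw0 <- consensus_weights(c(0, 0, 0))
  expect_equal(cw0$omega, 0)
  expect_equal(cw0$alpha[1, ], c(0, 0, 0))
})

test_that("consensus is convex, dominance-weighted and sign-conflict shrinking", {
  set.seed(21)
  W <- matrix(runif(3000 * 4, -1, 1), 3000)
  om <- consensus_weights(W)$omega
  expect_true(all(om >= apply(W, 1, min) - 1e-12))
  expect_true(all(om <= apply(W, 1, max) + 1e-12))
  expect_true(all(abs(om) <= apply(abs(W), 1, max) + 1e-12))
  # contribution weights sum to one whenever any magnitude is nonzero
  al <- consensus_weights(W)$alpha
  expect_true(all(abs(rowSums(al) - 1) < 1e-12))

  # same-sign pairs land above the arithmetic mean, toward the stronger net
  set.seed(22)
  a <- runif(200, 0.5, 1); b <- runif(200, 0.01, 0.49)
  expect_true(all(consensus_weights(cbind(a, b))$omega > (a + b) / 2))

  # flipping one sign strictly shrinks the magnitude
  W2 <- cbind(a, b)
  W2_flip <- cbind(a, -b)
  expect_true(all(abs(consensus_weights(W2_flip)$omega) <
                  abs(consensus_weights(W2)$omega)))
})

test_that("Fisher combination matches the closed-form chi-square tail", {
  expect_equal(fisher_combine(c(1, 1)), 1)
  # even df closed form: p = exp(-X/2) * (1 + X/2) for k = 2
  X <- -2 * sum(log(c(0.5, 0.5)))
  expect_equal(fisher_combine(c(0.5, 0.5)), exp(-X / 2) * (1 + X / 2))
  expect_equal(fisher_combine(c(0.5, 0.5)), 0.5966, tolerance = 1e-4)
  expect_equal(fisher_combine(0.123), 0.123)  # k = 1 identity
  expect_error(fisher_combine(c(0, 0.5)), "floor")
  # monotone in each input
  expect_lt(fisher_combine(c(0.01, 0.5)), fisher_combine(c(0.05, 0.5)))
})

test_that("node alignment drops nodes absent from any network", {
  full <- edge_df(c("A", "A", "B"), c("B", "C", "C"), c(0.5, 0.4, 0.3))
  noA <- edge_df("B", "C", 0.3)
  cn <- wto_consensus(list(full, full, full, noA))
  expect_false("A" %in% c(cn$edges$Node.1, cn$edges$Node.2))
  expect_equal(cn$nodes, c("B", "C"))

  # identical node sets: every pair survives
  cn2 <- wto_consensus(list(full, full))
  expect_equal(nrow(cn2$edges), 3)

  # two networks sharing 3 of 5 nodes
  n1 <- edge_df(c("A", "A", "B", "D"), c("B", "C", "C", "E"),
                c(0.5, 0.4, 0.3, 0.2))
  n2 <- edge_df(c("A", "B", "D"), c("B", "C", "X"), c(0.5, 0.3, 0.2))
  cn3 <- wto_consensus(list(n1, n2))
  expect_true(all(c(cn3$edges$Node.1, cn3$edges$Node.2) %in% c("A", "B", "C", "D")))
  expect_error(wto_consensus(list(edge_df("A", "B", 1), edge_df("X", "Y", 1))),
               "intersection")
})

test_that("missing links zero-fill by default and can be dropped", {
  n1 <- edge_df(c("A", "A"), c("B", "C"), c(0.6, 0.4))
  n2 <- edge_df(c("A", "B"), c("B", "C"), c(0.6, 0.1))  # A-C absent, C present
  cn_zero <- wto_consensus(list(n1, n2))
  ac <- cn_zero$edges[cn_zero$edges$Node.1 == "A" & cn_zero$edges$Node.2 == "C", ]
  expect_equal(nrow(ac), 1)
  expect_equal(ac$CN, 0.4)  # zero-filled network contributes nothing
  # drop mode keeps only pairs reported by every network
  cn_drop <- wto_consensus(list(n1, n2), missing_link = "drop")
  expect_equal(nrow(cn_drop$edges), 1)
  expect_equal(c(cn_drop$edges$Node.1, cn_drop$edges$Node.2), c("A", "B"))
})

test_that("significance filtering zeroes weights before combination", {
  # significant in 2 of 3 networks with equal |w|: consensus is their mean
  n1 <- edge_df("A", "B", 0.6, p = 0.001)
  n2 <- edge_df("A", "B", 0.6, p = 0.001)
  n3 <- edge_df("A", "B", 0.9, p = 0.5)
  cn <- wto_consensus(list(n1, n2, n3), alpha = 0.01)
  expect_equal(cn$edges$CN, 0.6)
  # alpha = 1 keeps everything
  cn_all <- wto_consensus(list(n1, n2, n3), alpha = 1)
  expect_gt(cn_all$edges$CN, 0.6)
  # adjusted p-values preferred when present
  n3$padj_sig <- 0.5; n3$pval_sig <- 0.001
  cn_adj <- wto_consensus(list(n1, n2, n3), alpha = 0.01)
  expect_equal(cn_adj$edges$CN, 0.6)
})

test_that("unanimous networks reproduce themselves and thresholding prunes", {
  set.seed(23)
  ids <- letters[1:6]
  prs <- t(combn(ids, 2))
  net <- edge_df(prs[, 1], prs[, 2], runif(nrow(prs), -1, 1),
                 p = runif(nrow(prs), 0.001, 0.05))
  cn <- wto_consensus(list(net, net, net), alpha = 1)
  expect_equal(cn$edges$CN, net$wTO_sign)

  expect_equal(nrow(threshold_consensus(cn, 0)$edges), nrow(net))
  expect_equal(nrow(threshold_consensus(cn, 1 + 1e-9)$edges), 0)

  # a sign-conflicting link falls below any reasonable threshold
  agree <- edge_df(c("D", "D"), c("E", "F"), c(0.8, 0.8))
  flip <- edge_df(c("D", "D"), c("E", "F"), c(-0.75, 0.8))
  cn2 <- wto_consensus(list(agree, agree, flip))
  de <- cn2$edges[cn2$edges$Node.2 == "E", "CN"]
  df_ <- cn2$edges[cn2$edges$Node.2 == "F", "CN"]
  expect_lt(abs(de), 0.35)
  expect_gt(df_, 0.7)
  kept <- threshold_consensus(cn2, 0.4)$edges
  expect_false("E" %in% kept$Node.2)
  expect_true("F" %in% kept$Node.2)
})

test_that("consensus p-values are Fisher-combined per link", {
  n1 <- edge_df("A", "B", 0.5, p = 0.5)
  n2 <- edge_df("A", "B", 0.5, p = 0.5)
  cn <- wto_consensus(list(n1, n2), alpha = 1)
  expect_equal(cn$edges$pval.fisher, 0.5966, tolerance = 1e-4)
  # zero p floored before logs
  n3 <- edge_df("A", "B", 0.5, p = 0)
  expect_silent(cn2 <- wto_consensus(list(n1, n3), alpha = 1, p_floor = 1e-3))
  expect_gt(cn2$edges$pval.fisher, 0)
})

test_that("A-B vs B-A rows unify, conflicting duplicates error", {
  tw <- data.frame(Node.1 = c("B", "A"), Node.2 = c("A", "C"),
                   wTO_sign = c(0.4, 0.2), pval_sig = 0.01)
  other <- edge_df(c("A", "A"), c("B", "C"), c(0.4, 0.2))
  cn <- wto_consensus(list(tw, other))
  expect_equal(cn$edges$Node.1, c("A", "A"))
  bad <- data.frame(Node.1 = c("A", "B"), Node.2 = c("B", "A"),
                    wTO_sign = c(0.4, 0.5), pval_sig = 0.01)
  expect_error(wto_consensus(list(bad, other)), "conflicting")
})
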