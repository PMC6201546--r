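test_that("correlation adjacency handles perfect, anti- and monotone correlation", {
  x <- c(1, 2, 3, 4, 5)
  m <- rbind(a = x, b = x, c = c(2, 0, 5, 1, 4))
  e <- expression_matrix(m)
  A <- correlation_adjacency(e)
  expect_equal(A["a", "b"], 1)
  expect_equal(diag(A), c(a = 0, b = 0, c = 0))

  m2 <- rbind(a = x, b = -x, c = c(2, 0, 5, 1, 4))
  for (method in c("pearson", "spearman")) {
    A2 <- correlation_adjacency(expression_matrix(m2), method = method)
    expect_equal(A2["a", "b"], -1)
  }

  # monotone nonlinear pair: rank correlation saturates, linear does not
  m3 <- rbind(a = x, b = x^2, c = c(2, 0, 5, 1, 4))
  As <- correlation_adjacency(expression_matrix(m3), method = "spearman")
  Ap <- correlation_adjacency(expression_matrix(m3), method = "pearson")
  expect_equal(As["a", "b"], 1)
  # textbook Pearson on (1..5) vs squares, evaluated by hand
  expect_equal(Ap["a", "b"], cov(x, x^2) / (sd(x) * sd(x^2)))
  expect_lt(Ap["a", "b"], 1)
})

test_that("absolute mode and zero-variance errors behave", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1), c = c(1, 3, 2, 4))
  A <- correlation_adjacency(expression_matrix(m), sign = "abs")
  expect_true(all(A >= 0 & A <= 1))
  expect_equal(diag(A), c(a = 0, b = 0, c = 0))

  e <- expression_matrix(m)
  e[2, ] <- 5  # degrade after validation
  expect_error(correlation_adjacency(e), "zero-variance.*b")
})

test_that("node strength matches brute-force absolute row sums", {
  A1 <- matrix(1, 3, 3); diag(A1) <- 0
  expect_equal(unname(node_strength(A1)), c(2, 2, 2))
  A2 <- matrix(-0.5, 3, 3); diag(A2) <- 0
  expect_equal(unname(node_strength(A2)), c(1, 1, 1))

  set.seed(42)
  A <- random_adjacency(10)
  brute <- sapply(seq_len(10), function(i) sum(abs(A[i, ])))
  expect_equal(unname(node_strength(A)), brute)
})

test_that("overlap reproduces hand-derived triangle values", {
  tri <- function(a12, a13, a23) {
    A <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
    A["x", "y"] <- A["y", "x"] <- a12
    A["x", "z"] <- A["z", "x"] <- a13
    A["y", "z"] <- A["z", "y"] <- a23
    A
  }
  # saturated triangle
  w <- wto_matrix(tri(1, 1, 1))
  expect_equal(w$omega_signed["x", "y"], 1)
  # coherent negative triangle
  w <- wto_matrix(tri(-1, 1, -1))
  expect_equal(w$omega_signed["x", "y"], -1)
  # cancellation triangle: signed shrinks, unsigned does not
  w <- wto_matrix(tri(0.5, 0.5, -0.5))
  expect_equal(w$omega_signed["x", "y"], 1 / 6)
  expect_equal(w$omega_abs["x", "y"], 0.5)
})

test_that("vectorized overlap equals the naive loop oracle", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(3:40, 1)
    A <- random_adjacency(n)
    w <- wto_matrix(A)
    expect_lt(max(abs(w$omega_signed - wto_loop(A))), 1e-10)
    expect_lt(max(abs(w$omega_abs - wto_loop(abs(A)))), 1e-10)
  }
})

test_that("bounds, dominance, relabeling and sign coherence hold", {
  set.seed(11)
  for (rep in 1:50) {
    A <- random_adjacency(sample(3:15, 1))
    w <- wto_matrix(A)
    expect_true(all(abs(w$omega_signed) <= 1 + 1e-12))
    expect_true(all(w$omega_abs >= -1e-12 & w$omega_abs <= 1 + 1e-12))
    expect_true(all(w$omega_abs - abs(w$omega_signed) >= -1e-12))
  }

  # permutation equivariance
  set.seed(3)
  A <- random_adjacency(8)
  perm <- sample(8)
  w_full <- wto_matrix(A)$omega_signed
  w_perm <- wto_matrix(A[perm, perm])$omega_signed
  expect_equal(w_perm, w_full[perm, perm])

  # single nonzero pair: overlap takes the sign of the correlation
  for (a in c(-0.7, 0.7)) {
    A1 <- matrix(0, 3, 3); A1[1, 2] <- A1[2, 1] <- a
    rownames(A1) <- colnames(A1) <- c("p", "q", "r")
    expect_equal(sign(wto_matrix(A1)$omega_signed["p", "q"]), sign(a))
  }
})

test_that("subset restricts reporting but never the sums", {
  set.seed(5)
  A <- random_adjacency(12)
  ids <- rownames(A)
  sub <- ids[c(2, 5, 9)]
  w_all <- wto_matrix(A)
  w_sub <- wto_matrix(A, sub)
  expect_equal(w_sub$omega_signed, w_all$omega_signed[sub, sub])
  expect_equal(nrow(w_sub$edges), 3)
  expect_false(any(w_sub$edges$Node.1 == w_sub$edges$Node.2))
  expect_error(wto_matrix(A, c(sub, "nope")), "nope")
  expect_error(wto_matrix(A, sub[1]), "at least 2")
})

test_that("self-overlap follows its defining ratio", {
  A <- matrix(0, 4, 4)
  rownames(A) <- colnames(A) <- letters[1:4]
  expect_equal(wto_self(A, "a"), 0)  # isolated node

  # binary star: hub of degree k gives k/(k+1)
  for (k in 1:3) {
    B <- matrix(0, 4, 4, dimnames = dimnames(A))
    B[1, 1 + seq_len(k)] <- B[1 + seq_len(k), 1] <- 1
    expect_equal(wto_self(B, "a"), k / (k + 1))
  }

  set.seed(9)
  C <- random_adjacency(7, negative = FALSE)
  i <- 3
  expect_equal(wto_self(C, i), sum(C[i, ]^2) / (sum(abs(C[i, ])) + 1))
})

test_that("expression matrix validation rejects bad input", {
  expect_error(expression_matrix(matrix(1:4, 2, 2)), "at least 3")
  m <- matrix(rnorm(12), 3, 4, dimnames = list(c("a", "a", "b"), NULL))
  expect_error(expression_matrix(m), "duplicate")
  m2 <- matrix(rnorm(12), 3, 4); m2[1, 1] <- NA
  expect_error(expression_matrix(m2), "missing")
  m3 <- rbind(a = rep(1, 4), b = rnorm(4), c = rnorm(4), d = rnorm(4))
  expect_warning(e <- expression_matrix(m3), "zero-variance")
  expect_equal(nrow(e), 3)
})
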