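# Shared oracles and generators, deliberately naive so they stay independent
# of the vectorized implementation they check.

# Random symmetric adjacency with zero diagonal, entries in [-1, 1].
random_adjacency <- function(n, negative = TRUE) {
  lo <- if (negative) -1 else 0
  A <- matrix(stats::runif(n * n, lo, 1), n, n)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  rownames(A) <- colnames(A) <- sprintf("n%02d", seq_len(n))
  A
}

# Triple-loop evaluation of the overlap ratio, literal transcription of the
# defining formula.
wto_loop <- function(A) {
  N <- nrow(A)
  k <- numeric(N)
  for (i in seq_len(N)) for (j in seq_len(N)) k[i] <- k[i] + abs(A[i, j])
  w <- matrix(0, N, N, dimnames = dimnames(A))
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    num <- A[i, j]
    for (u in seq_len(N)) num <- num + A[i, u] * A[u, j]
    w[i, j] <- num / (min(k[i], k[j]) + 1 - abs(A[i, j]))
  }
  w
}

# Hand step-up FDR adjustment for cross-checking adjust_pvalues().
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (r in m:1) {
    running <- min(running, m * p[o[r]] / r)
    adj[o[r]] <- min(1, running)
  }
  adj
}

lag1_acf <- function(x) {
  x <- x - mean(x)
  sum(x[-1] * x[-length(x)]) / sum(x^2)
}
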