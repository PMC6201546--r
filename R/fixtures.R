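#' Synthetic expression data with planted module structure
#'
#' Draws a node x sample matrix from a multivariate normal whose
#' correlation matrix has a planted block structure: `rho_within` inside
#' each module, `rho_between` across modules, unit variances. An optional
#' fraction of nodes has its profile negated, creating negative
#' within-module correlations that exercise signed-overlap code paths. The
#' implied correlation matrix is checked for positive semi-definiteness
#' before sampling.
#'
#' This generator stands in for real expression studies in all tests: it
#' reproduces the block-correlation skeleton of co-regulated gene modules,
#' but not library-size effects, heavy tails or count noise of real
#' RNA-seq data.
#'
#' @param n_nodes number of nodes (rows).
#' @param n_samples number of samples (columns).
#' @param n_modules number of equal-sized planted modules.
#' @param rho_within within-module correlation, in `[0, 1)`.
#' @param rho_between between-module correlation.
#' @param neg_fraction fraction of nodes whose profile is negated.
#' @param seed integer seed; the fixture is fully determined by the
#'   arguments plus the seed.
#' @return an [expression_matrix()] with attribute `"modules"`: the planted
#'   module label (integer) of each node, named by node id.
#' @examples
#' e <- make_block_expression(20, 50, n_modules = 2, rho_within = 0.7, seed = 1)
#' table(attr(e, "modules"))
#' @export
make_block_expression <- function(n_nodes = 60, n_samples = 100,
                                  n_modules = 2, rho_within = 0.7,
                                  rho_between = 0, neg_fraction = 0,
                                  seed = 1L) {
  stopifnot(n_nodes >= 3, n_samples >= 3, n_modules >= 1,
            rho_within >= 0, rho_within < 1,
            neg_fraction >= 0, neg_fraction <= 1)
  modules <- rep(seq_len(n_modules), length.out = n_nodes)
  modules <- sort(modules)
  Sigma <- matrix(rho_between, n_nodes, n_nodes)
  same <- outer(modules, modules, "==")
  Sigma[same] <- rho_within
  diag(Sigma) <- 1
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("implied correlation matrix is not positive semi-definite ",
         "(smallest eigenvalue ", signif(min(ev), 3), ")", call. = FALSE)
  set.seed(as.integer(seed))
  R <- chol(Sigma + diag(1e-10, n_nodes))
  X <- t(matrix(stats::rnorm(n_samples * n_nodes), n_samples) %*% R)
  if (neg_fraction > 0) {
    flip <- sample.int(n_nodes, floor(neg_fraction * n_nodes))
    X[flip, ] <- -X[flip, ]
  }
  rownames(X) <- sprintf("N%03d", seq_len(n_nodes))
  colnames(X) <- sprintf("S%03d", seq_len(n_samples))
  out <- expression_matrix(X)
  attr(out, "modules") <- stats::setNames(modules, rownames(X))
  out
}

#' Synthetic autoregressive time-series data
#'
#' Each node follows a stationary AR(1) process
#' \eqn{x_t = \phi x_{t-1} + \epsilon_t} with unit-variance innovations,
#' started from the stationary distribution (marginal variance
#' \eqn{1/(1-\phi^2)}). Innovations may be cross-correlated in planted
#' modules, giving temporally autocorrelated *and* co-varying rows — the
#' regime the blocked bootstrap is designed for.
#'
#' @inheritParams make_block_expression
#' @param phi AR(1) coefficient, `|phi| < 1`.
#' @param rho_within innovation correlation within modules (0 for
#'   independent rows).
#' @return an [expression_matrix()] with `time_series = TRUE` and the
#'   planted `"modules"` attribute.
#' @export
make_ar1_series <- function(n_nodes = 10, n_samples = 100, phi = 0.8,
                            n_modules = 1, rho_within = 0, seed = 1L) {
  stopifnot(abs(phi) < 1)
  modules <- sort(rep(seq_len(n_modules), length.out = n_nodes))
  set.seed(as.integer(seed))
  if (rho_within > 0) {
    Sigma <- matrix(0, n_nodes, n_nodes)
    Sigma[outer(modules, modules, "==")] <- rho_within
    diag(Sigma) <- 1
    R <- chol(Sigma + diag(1e-10, n_nodes))
    innov <- function() as.numeric(stats::rnorm(n_nodes) %*% R)
  } else {
    innov <- function() stats::rnorm(n_nodes)
  }
  X <- matrix(0, n_nodes, n_samples)
  X[, 1L] <- innov() / sqrt(1 - phi^2)
  for (t in 2:n_samples) X[, t] <- phi * X[, t - 1L] + innov()
  rownames(X) <- sprintf("N%03d", seq_len(n_nodes))
  colnames(X) <- sprintf("T%03d", seq_len(n_samples))
  out <- expression_matrix(X, time_series = TRUE)
  attr(out, "modules") <- stats::setNames(modules, rownames(X))
  out
}
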