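#' Correlation adjacency matrix
#'
#' Builds the adjacency \eqn{A = [a_{ij}]} of a co-expression network as the
#' pairwise correlation between node profiles, with the diagonal forced to
#' zero so that a node carries no self-adjacency. Pearson captures linear
#' association; Spearman (Pearson on average ranks) is preferred for
#' monotone, skewed or ordinal data. In `sign = "abs"` mode the entrywise
#' absolute value is taken after zeroing the diagonal, yielding the unsigned
#' network.
#'
#' @param expr an [expression_matrix()] (rows = nodes, columns = samples).
#' @param method correlation measure, `"pearson"` (default) or `"spearman"`.
#' @param sign `"signed"` (default) keeps correlation signs; `"abs"` takes
#'   absolute values.
#' @return symmetric N x N numeric matrix with zero diagonal and entries in
#'   \eqn{[-1, 1]} (in \eqn{[0, 1]} for `sign = "abs"`), rownames/colnames
#'   the node ids.
#' @examples
#' e <- expression_matrix(matrix(rnorm(40), 4, 10))
#' A <- correlation_adjacency(e)
#' all(diag(A) == 0)
#' @export
correlation_adjacency <- function(expr,
                                  method = c("pearson", "spearman"),
                                  sign = c("signed", "abs")) {
  method <- match.arg(method)
  sign <- match.arg(sign)
  v <- apply(expr, 1L, stats::var)
  if (any(v == 0))
    stop("zero-variance node(s): ",
         paste(rownames(expr)[v == 0], collapse = ", "), call. = FALSE)
  A <- stats::cor(t(unclass(expr)), method = method)
  diag(A) <- 0
  if (sign == "abs") A <- abs(A)
  A
}

#' Node strength
#'
#' The strength \eqn{k_i = \sum_j |a_{ij}|} of each node: the sum of
#' absolute adjacency over all partners. Enters the topological-overlap
#' denominator.
#'
#' @param A adjacency matrix (symmetric, zero diagonal).
#' @return nonnegative numeric vector of length N, named by node.
#' @export
node_strength <- function(A) {
  check_adjacency(A)
  colSums(abs(A))
}

check_adjacency <- function(A) {
  if (!is.matrix(A) || !is.numeric(A) || nrow(A) != ncol(A))
    stop("adjacency must be a square numeric matrix", call. = FALSE)
  if (max(abs(A - t(A))) > 1e-8)
    stop("adjacency must be symmetric", call. = FALSE)
  if (any(abs(diag(A)) > 1e-12))
    stop("adjacency diagonal must be zero", call. = FALSE)
  if (max(abs(A)) > 1 + 1e-8)
    stop("adjacency entries must lie in [-1, 1]", call. = FALSE)
  invisible(A)
}

#' Signed and unsigned weighted topological overlap
#'
#' For every unordered pair of nodes in `subset`, computes the weighted
#' topological overlap
#' \deqn{\omega_{ij} = \frac{\sum_{u=1}^{N} a_{iu} a_{uj} + a_{ij}}
#'                         {\min(k_i, k_j) + 1 - |a_{ij}|},}
#' where \eqn{k_i = \sum_j |a_{ij}|} and the sum runs over *all* N nodes of
#' the system — restricting to a subset of interest only restricts which
#' pairs are reported, never the sums. Because the adjacency keeps
#' correlation signs, \eqn{\omega} can be negative, distinguishing
#' co-activation from opposed regulation. The unsigned overlap is the same
#' formula applied to \eqn{|a_{ij}|}; term cancellation in the signed
#' numerator guarantees \eqn{|\omega^{signed}| \le \omega^{unsigned}}.
#'
#' The denominator is zero only when both nodes are connected solely to each
#' other with \eqn{|a_{ij}| = 1}; by continuity \eqn{\omega_{ij} = a_{ij}}
#' there.
#'
#' @param A signed adjacency matrix (see [correlation_adjacency()]).
#' @param subset character vector of node ids to report (>= 2), or `NULL`
#'   for all nodes.
#' @return list with components `omega_signed` and `omega_abs` (M x M
#'   symmetric matrices over the subset, zero diagonal) and `edges`, a
#'   data.frame with columns `Node.1`, `Node.2`, `wTO_sign`, `wTO_abs`, one
#'   row per unordered pair (endpoints in lexicographic order).
#' @examples
#' A <- matrix(c(0, .5, .5, .5, 0, -.5, .5, -.5, 0), 3, 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' wto_matrix(A)$edges
#' @export
wto_matrix <- function(A, subset = NULL) {
  check_adjacency(A)
  ids <- rownames(A)
  if (is.null(ids)) ids <- rownames(A) <- colnames(A) <- paste0("N", seq_len(nrow(A)))
  if (is.null(subset)) subset <- ids
  missing <- setdiff(subset, ids)
  if (length(missing))
    stop("subset ids not in adjacency: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(subset) < 2L)
    stop("need at least 2 nodes of interest", call. = FALSE)
  s <- match(subset, ids)
  omega_signed <- wto_core(A, s)
  omega_abs <- wto_core(abs(A), s)
  edges <- edge_list(omega_signed, omega_abs)
  list(omega_signed = omega_signed, omega_abs = omega_abs, edges = edges)
}

# Vectorized overlap over subset indices s; numerator via matrix product so
# the full-system sum is accumulated in one BLAS call.
wto_core <- function(A, s) {
  k <- colSums(abs(A))
  Ass <- A[s, s, drop = FALSE]
  num <- A[s, , drop = FALSE] %*% A[, s, drop = FALSE] + Ass
  den <- outer(k[s], k[s], pmin) + 1 - abs(Ass)
  w <- num / den
  degenerate <- den == 0
  if (any(degenerate)) w[degenerate] <- Ass[degenerate]
  diag(w) <- 0
  w <- (w + t(w)) / 2   # symmetrize away rounding asymmetry
  w
}

# Upper-triangle edge list with lexicographically ordered endpoints.
edge_list <- function(omega_signed, omega_abs) {
  ids <- rownames(omega_signed)
  ut <- which(upper.tri(omega_signed), arr.ind = TRUE)
  n1 <- ids[ut[, 1L]]
  n2 <- ids[ut[, 2L]]
  swap <- n1 > n2
  tmp <- n1[swap]; n1[swap] <- n2[swap]; n2[swap] <- tmp
  df <- data.frame(Node.1 = n1, Node.2 = n2,
                   wTO_sign = omega_signed[ut],
                   wTO_abs = omega_abs[ut],
                   stringsAsFactors = FALSE)
  df[order(df$Node.1, df$Node.2), , drop = FALSE] -> df
  rownames(df) <- NULL
  df
}

#' Self-overlap diagnostic
#'
#' The topological overlap of a node with itself,
#' \eqn{\omega_{ii} = \sum_u a_{iu}^2 / (k_i + 1)} with
#' \eqn{k_i = \sum_u |a_{iu}|}. For an unweighted network a node of degree k
#' gives \eqn{k/(k+1)}, approaching 1 for hubs; for weighted networks the
#' value stays informative rather than being pinned to 1. Diagnostic only —
#' self-pairs never appear in edge lists.
#'
#' @param A adjacency matrix.
#' @param node a node id (or integer index).
#' @return scalar self-overlap.
#' @export
wto_self <- function(A, node) {
  check_adjacency(A)
  if (is.character(node)) {
    i <- match(node, rownames(A))
    if (is.na(i)) stop("unknown node: ", node, call. = FALSE)
  } else i <- as.integer(node)
  a <- A[i, ]
  sum(a^2) / (sum(abs(a)) + 1)
}
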