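#' Consensus of several wTO networks
#'
#' Aggregates k >= 2 networks — biological replicates or independent
#' studies of the same system — into one consensus network. Each link's
#' consensus weight is the magnitude-weighted convex combination
#' \deqn{\Omega_{ij} = \sum_k \alpha^k_{ij}\, \omega^k_{ij}, \qquad
#'       \alpha^k_{ij} = \frac{|\omega^k_{ij}|}{\sum_k |\omega^k_{ij}|},}
#' which pulls \eqn{\Omega} toward the strongest input network when signs
#' agree and shrinks sign-conflicting links toward zero. Per-link p-values
#' are combined with Fisher's method. Nodes absent from any input network
#' are dropped (no consensus can be computed for links of an unmeasured
#' factor); a link missing from some networks while both endpoints are
#' present is treated as \eqn{\omega = 0, p = 1} there by default.
#'
#' @param networks a list of two or more networks: [wto_network()] fits or
#'   data.frames with columns node 1, node 2, weight, p-value (the
#'   significance-table columns `Node.1`, `Node.2`, `wTO_sign`, `pval_sig`
#'   are picked up automatically; adjusted p-values `padj_sig` are used for
#'   the significance filter when present).
#' @param alpha links with (adjusted, if available) p above `alpha` get
#'   their weight zeroed before combination, so insignificant links
#'   contribute nothing; `alpha = 1` disables the filter.
#' @param threshold links with \eqn{|\Omega|} below this value are removed
#'   from the output (0 keeps everything).
#' @param missing_link `"zero"` (default) treats a pair absent from a
#'   subset of networks as weight 0, p 1 there; `"drop"` removes such pairs
#'   entirely.
#' @param p_floor p-values of 0 are replaced by this before taking logs in
#'   Fisher's method; default `1e-4`, the resolution of a 10,000-resample
#'   empirical p. Set to `1/n_resamples` to match your resampling depth.
#' @param adjust_combined apply Benjamini-Hochberg to the combined p-values
#'   (off by default; the raw Fisher p is the primary output).
#' @return object of class `"wto_consensus"`: list with `edges`
#'   (`Node.1`, `Node.2`, `CN`, `pval.fisher`, and per-network weight
#'   columns), `nodes`, `k`, `config`.
#' @examples
#' n1 <- data.frame(Node.1 = "a", Node.2 = "b", wTO_sign = 0.8, pval_sig = 0.01)
#' n2 <- data.frame(Node.1 = "a", Node.2 = "b", wTO_sign = 0.2, pval_sig = 0.02)
#' wto_consensus(list(n1, n2), alpha = 1)$edges
#' @export
wto_consensus <- function(networks, alpha = 1, threshold = 0,
                          missing_link = c("zero", "drop"),
                          p_floor = 1e-4, adjust_combined = FALSE) {
  missing_link <- match.arg(missing_link)
  if (!is.list(networks) || length(networks) < 2L)
    stop("need a list of at least 2 networks", call. = FALSE)
  tables <- lapply(networks, consensus_table)
  k <- length(tables)

  node_sets <- lapply(tables, function(t) unique(c(t$Node.1, t$Node.2)))
  common <- Reduce(intersect, node_sets)
  if (length(common) < 2L)
    stop("node-set intersection too small (", length(common),
         " common node(s)); per-network node counts: ",
         paste(vapply(node_sets, length, 1L), collapse = ", "),
         call. = FALSE)
  tables <- lapply(tables, function(t)
    t[t$Node.1 %in% common & t$Node.2 %in% common, , drop = FALSE])

  # significance filter: zero the weight, keep the p for Fisher
  tables <- lapply(tables, function(t) {
    pcol <- if ("padj" %in% names(t) && !all(is.na(t$padj))) t$padj else t$pval
    t$weight[pcol > alpha] <- 0
    t
  })

  key <- function(t) paste(t$Node.1, t$Node.2, sep = "\r")
  all_keys <- sort(unique(unlist(lapply(tables, key))))
  W <- matrix(0, length(all_keys), k)
  P <- matrix(1, length(all_keys), k)
  present <- matrix(FALSE, length(all_keys), k)
  for (j in seq_len(k)) {
    idx <- match(key(tables[[j]]), all_keys)
    W[idx, j] <- tables[[j]]$weight
    P[idx, j] <- tables[[j]]$pval
    present[idx, j] <- TRUE
  }
  if (missing_link == "drop") {
    keep <- rowSums(present) == k
    all_keys <- all_keys[keep]
    W <- W[keep, , drop = FALSE]
    P <- P[keep, , drop = FALSE]
  }

  cw <- consensus_weights(W)
  P[P <= 0] <- p_floor
  p_comb <- apply(P, 1L, fisher_combine)
  if (adjust_combined) p_comb <- adjust_pvalues(p_comb, "BH")

  parts <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
  edges <- data.frame(Node.1 = parts[, 1L], Node.2 = parts[, 2L],
                      CN = cw$omega, pval.fisher = p_comb,
                      stringsAsFactors = FALSE)
  wcols <- as.data.frame(W)
  names(wcols) <- paste0("wTO_", seq_len(k))
  edges <- cbind(edges, wcols)
  keep <- abs(edges$CN) >= threshold
  edges <- edges[keep, , drop = FALSE]
  rownames(edges) <- NULL

  structure(list(edges = edges, nodes = sort(common), k = k,
                 config = list(alpha = alpha, threshold = threshold,
                               missing_link = missing_link,
                               p_floor = p_floor,
                               adjust_combined = adjust_combined)),
            class = "wto_consensus")
}

# Normalize any accepted input to Node.1/Node.2/weight/pval(/padj) with
# lexicographically ordered endpoints and unique pairs.
consensus_table <- function(x) {
  if (inherits(x, "wto_network")) x <- x$edges
  x <- as.data.frame(x)
  nm <- names(x)
  pick <- function(cands, default = NA) {
    hit <- cands[cands %in% nm]
    if (length(hit)) hit[1L] else default
  }
  c1 <- pick(c("Node.1", "node1", "Node1"))
  c2 <- pick(c("Node.2", "node2", "Node2"))
  cw <- pick(c("wTO_sign", "weight", "wTO", "CN"))
  cp <- pick(c("pval_sig", "pval", "p", "pval.fisher"))
  ca <- pick(c("padj_sig", "padj"))
  if (is.na(c1) || is.na(c2) || is.na(cw) || is.na(cp)) {
    if (ncol(x) < 4L)
      stop("edge table needs node1, node2, weight and p-value columns",
           call. = FALSE)
    c1 <- nm[1L]; c2 <- nm[2L]; cw <- nm[3L]; cp <- nm[4L]; ca <- NA
  }
  out <- data.frame(Node.1 = as.character(x[[c1]]),
                    Node.2 = as.character(x[[c2]]),
                    weight = as.numeric(x[[cw]]),
                    pval = as.numeric(x[[cp]]),
                    padj = if (!is.na(ca)) as.numeric(x[[ca]]) else NA_real_,
                    stringsAsFactors = FALSE)
  if (any(out$weight < -1 - 1e-8 | out$weight > 1 + 1e-8))
    stop("link weights must lie in [-1, 1]", call. = FALSE)
  if (any(out$pval < 0 | out$pval > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  swap <- out$Node.1 > out$Node.2
  if (any(swap)) {
    tmp <- out$Node.1[swap]
    out$Node.1[swap] <- out$Node.2[swap]
    out$Node.2[swap] <- tmp
  }
  out <- out[out$Node.1 != out$Node.2, , drop = FALSE]
  kk <- paste(out$Node.1, out$Node.2)
  if (anyDuplicated(kk)) {
    dup <- kk[duplicated(kk)]
    grp <- out[kk %in% dup, , drop = FALSE]
    agg <- tapply(grp$weight, paste(grp$Node.1, grp$Node.2),
                  function(w) diff(range(w)))
    if (any(agg > 1e-12))
      stop("conflicting duplicate pairs (A-B vs B-A with different weights): ",
           paste(names(agg)[agg > 1e-12], collapse = ", "), call. = FALSE)
    out <- out[!duplicated(kk), , drop = FALSE]
  }
  out
}

#' Consensus weights for a link across networks
#'
#' Low-level kernel of [wto_consensus()]: given a links x networks weight
#' matrix, returns the convex combination \eqn{\Omega} and the contribution
#' weights \eqn{\alpha}. When every network reports 0 for a link,
#' \eqn{\Omega = 0} and the contributions are reported as zeros.
#'
#' @param W numeric matrix (or vector, treated as one link), links x k.
#' @return list with `omega` (length-links vector) and `alpha`
#'   (links x k matrix).
#' @export
consensus_weights <- function(W) {
  if (is.vector(W)) W <- matrix(W, nrow = 1L)
  tot <- rowSums(abs(W))
  alpha <- abs(W) / ifelse(tot == 0, 1, tot)
  omega <- rowSums(alpha * W)
  list(omega = omega, alpha = alpha)
}

#' Fisher's method for combining p-values
#'
#' \eqn{X = -2\sum_k \log p_k} follows a chi-square distribution with 2k
#' degrees of freedom under the joint null; the combined p is its upper
#' tail at X.
#'
#' @param p vector of p-values, each in `(0, 1]`. Zeros must be floored by
#'   the caller (see the `p_floor` argument of [wto_consensus()]).
#' @return combined p-value.
#' @export
fisher_combine <- function(p) {
  if (any(p <= 0))
    stop("Fisher combination needs p > 0; floor zero p-values first",
         call. = FALSE)
  if (any(p > 1)) stop("p-values must not exceed 1", call. = FALSE)
  X <- -2 * sum(log(p))
  stats::pchisq(X, df = 2 * length(p), lower.tail = FALSE)
}

#' Remove weak consensus links
#'
#' Drops links whose consensus weight is closer to zero than
#' `min_abs_omega` — typically the residue of sign conflicts between the
#' input networks.
#'
#' @param cn a [wto_consensus()] object.
#' @param min_abs_omega nonnegative threshold on \eqn{|\Omega|}.
#' @return the consensus object with weak links removed.
#' @export
threshold_consensus <- function(cn, min_abs_omega) {
  stopifnot(inherits(cn, "wto_consensus"), min_abs_omega >= 0)
  cn$edges <- cn$edges[abs(cn$edges$CN) >= min_abs_omega, , drop = FALSE]
  rownames(cn$edges) <- NULL
  cn$config$threshold <- max(cn$config$threshold, min_abs_omega)
  cn
}

#' @export
print.wto_consensus <- function(x, ...) {
  cat(sprintf("Consensus of %d wTO networks: %d nodes, %d links\n",
              x$k, length(x$nodes), nrow(x$edges)))
  cat(sprintf("  |CN| range: [%.4f, %.4f]; links with Fisher p <= 0.01: %d\n",
              if (nrow(x$edges)) min(abs(x$edges$CN)) else NA,
              if (nrow(x$edges)) max(abs(x$edges$CN)) else NA,
              sum(x$edges$pval.fisher <= 0.01)))
  invisible(x)
}

#' @export
as.data.frame.wto_consensus <- function(x, ...) x$edges

#' @export
summary.wto_consensus <- function(object, ...) {
  e <- object$edges
  cat(sprintf("Consensus network over %d input networks\n", object$k))
  cat(sprintf("  nodes: %d, links: %d\n", length(object$nodes), nrow(e)))
  if (nrow(e)) {
    cat("  CN distribution:\n")
    print(summary(e$CN))
  }
  invisible(object)
}
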