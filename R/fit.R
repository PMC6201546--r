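#' Fit a weighted topological overlap network
#'
#' The main entry point: builds the correlation adjacency of the full
#' system, computes signed and unsigned weighted topological overlap for
#' every pair of nodes of interest, and (optionally) attaches per-link
#' p-values by resampling the samples. Returns a classed object with
#' `print`, `summary`, `coef`, `plot` and `as.data.frame` methods.
#'
#' Resampling schemes:
#' * `"bootstrap"` — resample samples with replacement; the p-value is the
#'   delta-band instability fraction
#'   \eqn{P(|\omega^* - \hat\omega| \ge \delta)} (see
#'   [pvalues_bootstrap()]). A stability measure, not a classical test.
#' * `"block_bootstrap"` — moving-block bootstrap for replicate-free time
#'   series; `lag` is the block length (use [suggest_lag()] if unsure).
#'   Same delta-band p-value.
#' * `"reshuffle"` — permute values across nodes within each sample,
#'   yielding a genuine null distribution of \eqn{\omega} under
#'   independence; two-sided add-one permutation p-values.
#' * `"none"` (or `n = 0`) — plain wTO values, no p-values.
#'
#' Reproducibility contract: with a given `seed`, results are bit-identical
#' regardless of `threads` — each resample draws from its own seed derived
#' from the master seed by resample index, so worker scheduling cannot
#' change anything.
#'
#' Bootstrap p-values of exactly 0 (every resample inside the band) are
#' floored at `1/n` so that downstream log-based combination (Fisher's
#' method in [wto_consensus()]) is well defined; `1/n` is the resolution of
#' an n-resample empirical probability.
#'
#' @param expr an [expression_matrix()], or a plain numeric matrix with
#'   node rownames (rows = nodes, columns = samples).
#' @param subset character vector of node ids of interest (e.g. the
#'   transcription factors); `NULL` reports all pairs. All N nodes always
#'   contribute to every score's sums.
#' @param method correlation measure, `"pearson"` or `"spearman"`.
#' @param resampling one of `"bootstrap"`, `"block_bootstrap"`,
#'   `"reshuffle"`, `"none"`.
#' @param n number of resamples (typically 1000 for production use).
#' @param delta stability band for bootstrap p-values, in `(0, 1]`.
#' @param lag block length for `"block_bootstrap"`.
#' @param adjust multiple-testing correction, `"BH"` (default),
#'   `"bonferroni"` or `"holm"`.
#' @param seed integer master seed for all resampling randomness.
#' @param threads number of worker processes for the resampling loop.
#' @param keep_correlation keep the full node-by-node correlation table in
#'   the result (`FALSE` by default; it is quadratic in N).
#' @param keep_null keep the per-link resampled weight matrices
#'   (links x n) in the result, for diagnostics.
#' @return an object of class `"wto_network"`: a list with `edges` (the
#'   significance table: `Node.1`, `Node.2`, `wTO_sign`, `wTO_abs` and,
#'   when resampling, `pval_sig`, `pval_abs`, `padj_sig`, `padj_abs`),
#'   `quantiles` (empirical quantile thresholds of the signed weights),
#'   `N`, `subset`, `config`, and optionally `correlation` and `null`.
#' @examples
#' e <- make_block_expression(n_nodes = 12, n_samples = 30, n_modules = 2,
#'                            rho_within = 0.6, seed = 1)
#' fit <- wto_network(e, resampling = "reshuffle", n = 50, seed = 1)
#' fit
#' head(as.data.frame(fit))
#' @export
wto_network <- function(expr, subset = NULL,
                        method = c("pearson", "spearman"),
                        resampling = c("bootstrap", "block_bootstrap",
                                       "reshuffle", "none"),
                        n = 100, delta = 0.2, lag = NULL,
                        adjust = c("BH", "bonferroni", "holm"),
                        seed = NULL, threads = 1L,
                        keep_correlation = FALSE, keep_null = FALSE) {
  method <- match.arg(method)
  resampling <- match.arg(resampling)
  adjust <- match.arg(adjust)
  if (!inherits(expr, "expression_matrix")) expr <- expression_matrix(expr)
  n <- as.integer(n)
  if (n == 0L) resampling <- "none"
  if (resampling == "block_bootstrap") {
    if (is.null(lag)) stop("block_bootstrap requires a lag; see suggest_lag()",
                           call. = FALSE)
    if (!is_time_series(expr))
      stop("block_bootstrap requires a time-series matrix ",
           "(expression_matrix(..., time_series = TRUE))", call. = FALSE)
  }
  if (resampling != "none") {
    if (n < 10L) stop("need at least 10 resamples", call. = FALSE)
    if (n < 100L) warning("fewer than 100 resamples; p-value resolution is ",
                          signif(1 / n, 2), call. = FALSE)
  }

  A <- correlation_adjacency(expr, method = method)
  w <- wto_matrix(A, subset)
  edges <- w$edges
  if (is.null(subset)) subset <- rownames(A)

  quantiles <- NULL
  null <- NULL
  if (resampling != "none") {
    resampler <- switch(resampling,
      bootstrap = resample_bootstrap,
      block_bootstrap = function(e) resample_block(e, lag),
      reshuffle = reshuffle)
    if (!is.null(seed)) set.seed(as.integer(seed))
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    one <- function(b) {
      set.seed(seeds[b])
      eb <- resampler(expr)
      Ab <- lenient_adjacency(eb, method)
      wb <- wto_matrix(Ab, subset)$edges
      cbind(wb$wTO_sign, wb$wTO_abs)
    }
    res <- if (threads > 1L && .Platform$OS.type == "unix")
      parallel::mclapply(seq_len(n), one, mc.cores = threads)
    else lapply(seq_len(n), one)
    null_sign <- vapply(res, function(m) m[, 1L], numeric(nrow(edges)))
    null_abs <- vapply(res, function(m) m[, 2L], numeric(nrow(edges)))
    if (nrow(edges) == 1L) {  # vapply drops to vector shape consistently
      null_sign <- matrix(null_sign, nrow = 1L)
      null_abs <- matrix(null_abs, nrow = 1L)
    }
    if (resampling == "reshuffle") {
      p_sig <- pvalues_permutation(edges$wTO_sign, null_sign)
      p_abs <- pvalues_permutation(edges$wTO_abs, null_abs)
    } else {
      p_sig <- pvalues_bootstrap(edges$wTO_sign, null_sign, delta)
      p_abs <- pvalues_bootstrap(edges$wTO_abs, null_abs, delta)
      p_sig[p_sig == 0] <- 1 / n
      p_abs[p_abs == 0] <- 1 / n
    }
    edges$pval_sig <- p_sig
    edges$pval_abs <- p_abs
    edges$padj_sig <- adjust_pvalues(p_sig, adjust)
    edges$padj_abs <- adjust_pvalues(p_abs, adjust)
    q_sign <- empirical_quantiles(edges$wTO_sign, null_sign)
    q_abs <- empirical_quantiles(edges$wTO_abs, null_abs)
    quantiles <- rbind(q_sign, q_abs)
    rownames(quantiles) <- c("resampled_sign", "observed_sign",
                             "resampled_abs", "observed_abs")
    if (keep_null) null <- list(signed = null_sign, abs = null_abs)
  } else {
    quantiles <- empirical_quantiles(edges$wTO_sign)
    rownames(quantiles) <- "observed_sign"
  }

  out <- list(edges = edges, quantiles = quantiles,
              N = nrow(A), subset = subset,
              config = list(method = method, resampling = resampling,
                            n = if (resampling == "none") 0L else n,
                            delta = delta, lag = lag, adjust = adjust,
                            seed = seed, threads = threads),
              call = match.call())
  if (keep_correlation) {
    A_full <- A
    out$correlation <- edge_list(A_full, abs(A_full))[, 1:3]
    names(out$correlation)[3L] <- "cor"
  }
  if (!is.null(null)) out$null <- null
  class(out) <- "wto_network"
  out
}

# Correlation adjacency tolerant of degenerate resamples: a column bootstrap
# can draw a constant row, whose correlations are undefined; they carry no
# association signal and enter the sums as 0.
lenient_adjacency <- function(expr, method) {
  A <- suppressWarnings(stats::cor(t(unclass(expr)), method = method))
  A[!is.finite(A)] <- 0
  diag(A) <- 0
  A
}

#' @export
print.wto_network <- function(x, ...) {
  cfg <- x$config
  cat("Weighted topological overlap network\n")
  cat(sprintf("  system: %d nodes, %d of interest, %d links\n",
              x$N, length(x$subset), nrow(x$edges)))
  cat(sprintf("  correlation: %s; resampling: %s", cfg$method, cfg$resampling))
  if (cfg$resampling != "none") {
    cat(sprintf(" (n = %d%s)", cfg$n,
                if (cfg$resampling %in% c("bootstrap", "block_bootstrap"))
                  sprintf(", delta = %g", cfg$delta) else ""))
  }
  cat("\n")
  if ("padj_sig" %in% names(x$edges))
    cat(sprintf("  links with padj_sig <= 0.01: %d\n",
                sum(x$edges$padj_sig <= 0.01)))
  invisible(x)
}

#' @export
summary.wto_network <- function(object, alpha = 0.01, ...) {
  e <- object$edges
  out <- list(
    n_nodes = object$N,
    n_interest = length(object$subset),
    n_links = nrow(e),
    wto_range = range(e$wTO_sign),
    config = object$config,
    quantiles = object$quantiles,
    alpha = alpha,
    n_significant = if ("padj_sig" %in% names(e))
      sum(e$padj_sig <= alpha) else NA_integer_
  )
  class(out) <- "summary.wto_network"
  out
}

#' @export
print.summary.wto_network <- function(x, ...) {
  cat(sprintf("wTO network: %d nodes (%d of interest), %d links\n",
              x$n_nodes, x$n_interest, x$n_links))
  cat(sprintf("  signed wTO range: [%.4f, %.4f]\n",
              x$wto_range[1], x$wto_range[2]))
  if (!is.na(x$n_significant))
    cat(sprintf("  significant links (padj_sig <= %g): %d\n",
                x$alpha, x$n_significant))
  cat("  quantile thresholds:\n")
  print(round(x$quantiles, 4))
  invisible(x)
}

#' Extract signed link weights
#'
#' Returns the signed wTO of every reported pair as a named vector
#' (`"node1|node2"`), the natural coefficient set of the fitted network.
#'
#' @param object a [wto_network()] fit.
#' @param ... unused.
#' @export
coef.wto_network <- function(object, ...) {
  e <- object$edges
  stats::setNames(e$wTO_sign, paste(e$Node.1, e$Node.2, sep = "|"))
}

#' @export
as.data.frame.wto_network <- function(x, ...) x$edges

#' Diagnostic plot of a wTO network
#'
#' Scatter of signed versus unsigned overlap: points on the |y| = |x|
#' diagonals are links untouched by term cancellation; departure toward the
#' horizontal axis indicates cancellation between positive and negative
#' co-regulation paths. If p-values are available a second panel shows
#' p against the signed weight.
#'
#' @param x a [wto_network()] fit.
#' @param ... passed to [plot()].
#' @export
plot.wto_network <- function(x, ...) {
  e <- x$edges
  has_p <- "pval_sig" %in% names(e)
  if (has_p) {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
  }
  plot(e$wTO_sign, e$wTO_abs, xlab = expression(omega),
       ylab = expression("|" * omega * "|"),
       main = "signed vs unsigned overlap", pch = 20, ...)
  graphics::abline(0, 1, lty = 2); graphics::abline(0, -1, lty = 2)
  if (has_p) {
    plot(e$wTO_sign, e$pval_sig, xlab = expression(omega), ylab = "p",
         main = "link significance", pch = 20, ...)
  }
  invisible(x)
}
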