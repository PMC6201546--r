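#' Bootstrap delta-band p-values
#'
#' The bootstrap significance measure is a *stability* probability, not a
#' classical null p-value: for each link it estimates
#' \eqn{p_{ij} = P(|\omega^*_{ij} - \hat\omega_{ij}| \ge \delta)}, the
#' chance that a resampled weight departs from the observed weight by at
#' least the band \eqn{\delta} (default 0.2). The smaller the fraction of
#' resamples outside the band, the stronger the confidence in the link.
#'
#' @param observed numeric vector of observed link weights (one per link).
#' @param resampled numeric matrix, links x resamples, of weights
#'   recomputed on resampled data, rows aligned with `observed`.
#' @param delta stability band, in `(0, 1]`.
#' @return numeric vector of p-values in `[0, 1]` (0 means every resample
#'   stayed inside the band; callers flooring for log-based combination
#'   should use `1/n`).
#' @export
pvalues_bootstrap <- function(observed, resampled, delta = 0.2) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta > 1)
    stop("delta must be a single value in (0, 1]", call. = FALSE)
  resampled <- as.matrix(resampled)
  if (nrow(resampled) != length(observed))
    stop("resampled rows must match the number of links", call. = FALSE)
  rowMeans(abs(resampled - observed) >= delta)
}

#' Permutation p-values
#'
#' Two-sided empirical p-value with the add-one correction:
#' \eqn{p_{ij} = (1 + \#\{b : |\omega^*_{ij}(b)| \ge |\hat\omega_{ij}|\})
#' / (n + 1)}. The correction keeps p strictly positive, preserving
#' finite-sample validity.
#'
#' @inheritParams pvalues_bootstrap
#' @return numeric vector of p-values in `(0, 1]`.
#' @export
pvalues_permutation <- function(observed, resampled) {
  resampled <- as.matrix(resampled)
  if (nrow(resampled) != length(observed))
    stop("resampled rows must match the number of links", call. = FALSE)
  n <- ncol(resampled)
  (1 + rowSums(abs(resampled) >= abs(observed))) / (n + 1)
}

#' Multiple-testing adjustment
#'
#' Thin wrapper over [stats::p.adjust()] restricted to the three procedures
#' the network pipeline offers; Benjamini-Hochberg (FDR) is the default.
#'
#' @param p numeric vector of p-values.
#' @param method one of `"BH"`, `"bonferroni"`, `"holm"`.
#' @return adjusted p-values, clipped to `[0, 1]`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni", "holm")) {
  method <- match.arg(method)
  stats::p.adjust(p, method = method)
}

#' Empirical quantile table
#'
#' Quantiles of the pooled resampled link-weight distribution and of the
#' observed distribution at 0.1%, 2.5%, 10%, 90%, 97.5% and 99.9%. These
#' serve as data-driven thresholds for pruning weak links. Type-7 (linear)
#' interpolation is used so results are bit-reproducible across platforms.
#'
#' @param observed numeric vector of observed signed weights.
#' @param resampled numeric matrix of resampled weights (may be `NULL`,
#'   yielding only the observed row).
#' @return data.frame, one row per distribution (`"resampled"`,
#'   `"observed"`), columns the six quantiles.
#' @export
empirical_quantiles <- function(observed, resampled = NULL) {
  probs <- c(0.001, 0.025, 0.10, 0.90, 0.975, 0.999)
  rows <- list()
  if (!is.null(resampled))
    rows$resampled <- stats::quantile(as.numeric(resampled), probs,
                                      type = 7, names = FALSE)
  rows$observed <- stats::quantile(as.numeric(observed), probs,
                                   type = 7, names = FALSE)
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- paste0(formatC(100 * probs, format = "fg"), "%")
  out
}
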