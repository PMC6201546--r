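#' Column resampling schemes
#'
#' Three ways of perturbing an expression matrix to gauge link stability or
#' build a null distribution:
#'
#' * `resample_bootstrap()` draws S samples (columns) with replacement —
#'   the classical bootstrap over individuals, approximating the empirical
#'   distribution of each link weight.
#' * `resample_block()` draws overlapping moving blocks of `lag` consecutive
#'   time points with replacement and concatenates them, truncated to S
#'   columns. For replicate-free time series this respects the
#'   autocorrelation structure a plain bootstrap would destroy; `lag = 1`
#'   degenerates to the plain bootstrap.
#' * `reshuffle()` permutes values across nodes within each sample
#'   independently, destroying all inter-node dependence while preserving
#'   every sample's value distribution — the permutation null.
#'
#' All three are driven by the session RNG; set a seed for reproducibility.
#'
#' @param expr an [expression_matrix()].
#' @param lag block length (number of consecutive time points), `1 <= lag < S`.
#' @return a resampled matrix of identical dimension (class preserved).
#' @name resampling
NULL

#' @rdname resampling
#' @export
resample_bootstrap <- function(expr) {
  S <- ncol(expr)
  idx <- sample.int(S, S, replace = TRUE)
  out <- expr[, idx, drop = FALSE]
  colnames(out) <- make.unique(colnames(expr)[idx])
  as_expr(out, expr)
}

#' @rdname resampling
#' @export
resample_block <- function(expr, lag) {
  if (!is_time_series(expr))
    stop("blocked bootstrap needs a time-series matrix; ",
         "use resample_bootstrap() for independent samples", call. = FALSE)
  S <- ncol(expr)
  lag <- as.integer(lag)
  if (lag < 1L || lag >= S)
    stop("lag must satisfy 1 <= lag < number of time points (", S, ")",
         call. = FALSE)
  n_blocks <- ceiling(S / lag)
  starts <- sample.int(S - lag + 1L, n_blocks, replace = TRUE)
  idx <- unlist(lapply(starts, function(s) s:(s + lag - 1L)))[seq_len(S)]
  out <- expr[, idx, drop = FALSE]
  colnames(out) <- make.unique(colnames(expr)[idx])
  as_expr(out, expr, time_series = TRUE)
}

#' @rdname resampling
#' @export
reshuffle <- function(expr) {
  out <- apply(unclass(expr), 2L, sample)
  dimnames(out) <- dimnames(expr)
  as_expr(out, expr, time_series = is_time_series(expr))
}

#' Suggest a block length from autocorrelation
#'
#' For each node, finds how far the sample autocorrelation stays above the
#' 95% white-noise band \eqn{1.96/\sqrt{S}} — the largest lag L such that
#' the autocorrelations at every lag 1..L exceed the band — then returns
#' the median over nodes (minimum 1). The consecutive-run rule captures
#' the window over which observations remain correlated, which is what a
#' bootstrap block must span; an isolated significant autocorrelation at a
#' long lag (expected by chance in 5% of lags even for white noise) does
#' not inflate the suggestion.
#'
#' @param expr a time-series [expression_matrix()].
#' @param max_lag largest lag to examine (default `10`).
#' @return integer suggested lag, at least 1.
#' @export
suggest_lag <- function(expr, max_lag = 10L) {
  if (!is_time_series(expr))
    stop("suggest_lag() applies to time-series matrices", call. = FALSE)
  S <- ncol(expr)
  max_lag <- min(as.integer(max_lag), S - 1L)
  band <- 1.96 / sqrt(S)
  per_row <- apply(unclass(expr), 1L, function(x) {
    r <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1L]
    run <- which(r <= band)
    if (!length(run)) max_lag else max(1L, run[1L] - 1L)
  })
  max(1L, as.integer(round(stats::median(per_row))))
}
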