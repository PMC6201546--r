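#' Construct and validate an expression matrix
#'
#' An expression matrix holds one row per node (gene, transcription factor,
#' OTU, metabolite, ...) and one column per sample (or time point). It is the
#' raw input to every network computation in this package. Values may be any
#' continuous or discrete abundance measure; normalisation and quality
#' control are expected to have happened upstream.
#'
#' Rows with zero variance are removed with a warning: a constant row has no
#' defined correlation with anything, and an undefined entry would propagate
#' through every topological-overlap sum.
#'
#' @param x numeric matrix (or object coercible to one) with at least 3 rows
#'   and 3 columns; rownames are node identifiers, colnames sample
#'   identifiers. Missing values are rejected.
#' @param time_series logical; `TRUE` declares the columns to be ordered
#'   time points, enabling the blocked bootstrap.
#' @return a numeric matrix of class `"expression_matrix"` with unique
#'   rownames, no missing values and no zero-variance rows; the
#'   `time_series` flag is stored as an attribute.
#' @examples
#' m <- matrix(rnorm(30), 5, 6,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
#' e <- expression_matrix(m)
#' is_time_series(e)
#' @export
expression_matrix <- function(x, time_series = FALSE) {
  x <- as.matrix(x)
  if (!is.numeric(x))
    stop("expression values must be numeric", call. = FALSE)
  if (is.null(rownames(x)))
    rownames(x) <- paste0("N", seq_len(nrow(x)))
  if (is.null(colnames(x)))
    colnames(x) <- paste0("S", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x)))
    stop("duplicate node ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  if (anyNA(x))
    stop("expression matrix contains missing values; impute or filter upstream",
         call. = FALSE)
  v <- apply(x, 1L, stats::var)
  if (any(v == 0)) {
    dropped <- rownames(x)[v == 0]
    warning("dropping ", length(dropped), " zero-variance row(s): ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "", call. = FALSE)
    x <- x[v > 0, , drop = FALSE]
  }
  if (nrow(x) < 3L || ncol(x) < 3L)
    stop("need at least 3 nodes and 3 samples after filtering (got ",
         nrow(x), " x ", ncol(x), ")", call. = FALSE)
  structure(x, time_series = isTRUE(time_series),
            class = c("expression_matrix", class(unclass(x))))
}

#' @rdname expression_matrix
#' @export
is_time_series <- function(x) isTRUE(attr(x, "time_series"))

# Re-wrap a resampled plain matrix, keeping the time-series flag optional.
as_expr <- function(values, template, time_series = FALSE) {
  structure(values, time_series = time_series,
            class = class(template))
}
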