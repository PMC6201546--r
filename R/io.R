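#' Read an expression matrix from delimited text
#'
#' Expects nodes in rows (first column = node id, header row = sample ids);
#' `transpose = TRUE` handles samples-in-rows files. The delimiter is
#' guessed from the extension (`.csv` = comma, otherwise tab) unless given.
#' Duplicate node ids, ragged rows and non-numeric cells are hard errors
#' with positional context; zero-variance rows are dropped with a warning
#' by the [expression_matrix()] validator.
#'
#' @param path file path.
#' @param sep field delimiter; `NULL` to guess from the extension.
#' @param transpose set `TRUE` when rows are samples and columns nodes.
#' @param time_series declare the columns to be ordered time points.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, sep = NULL, transpose = FALSE,
                            time_series = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate node id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop("non-numeric cell at row ", bad[1L], ", column '",
             names(vals)[j], "' of ", path, call. = FALSE)
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (transpose) m <- t(m)
  expression_matrix(m, time_series = time_series)
}

#' @rdname read_expression
#' @param expr the matrix to write.
#' @export
write_expression <- function(expr, path, sep = "\t") {
  df <- data.frame(Node = rownames(expr),
                   as.data.frame(unclass(expr), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write network edge tables
#'
#' The on-disk dialect is a TSV with header
#' `Node.1 Node.2 wTO_sign wTO_abs pval_sig pval_abs padj_sig padj_abs`
#' (columns beyond the first four optional); `cols` maps custom column
#' names or positions onto (node1, node2, weight, p-value). Pairs are
#' normalized to lexicographic endpoint order and checked for conflicting
#' duplicates; weights and p-values are range-validated.
#'
#' @param path file path.
#' @param sep field delimiter; `NULL` to guess from the extension.
#' @param cols optional length-4 character (names) or integer (positions)
#'   vector selecting node1, node2, weight, p-value columns.
#' @return data.frame of validated edges.
#' @export
read_edge_table <- function(path, sep = NULL, cols = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(cols)) {
    if (length(cols) < 4L)
      stop("cols must select node1, node2, weight, p-value", call. = FALSE)
    sel <- if (is.numeric(cols)) names(df)[cols] else cols
    df <- df[, sel, drop = FALSE]
    names(df)[1:4] <- c("Node.1", "Node.2", "wTO_sign", "pval_sig")
  }
  tab <- consensus_table(df)
  bad_w <- which(tab$weight < -1 | tab$weight > 1)
  if (length(bad_w))
    stop("weight out of [-1, 1] at row ", bad_w[1L], " of ", path,
         call. = FALSE)
  bad_p <- which(tab$pval < 0 | tab$pval > 1)
  if (length(bad_p))
    stop("p-value out of [0, 1] at row ", bad_p[1L], " of ", path,
         call. = FALSE)
  out <- data.frame(Node.1 = tab$Node.1, Node.2 = tab$Node.2,
                    wTO_sign = tab$weight, pval_sig = tab$pval,
                    stringsAsFactors = FALSE)
  if (!all(is.na(tab$padj))) out$padj_sig <- tab$padj
  extra <- setdiff(names(df), c("Node.1", "Node.2", "wTO_sign", "pval_sig",
                                "padj_sig"))
  keep_extra <- intersect(c("wTO_abs", "pval_abs", "padj_abs"), extra)
  for (cn in keep_extra) out[[cn]] <- df[[cn]][match(
    paste(out$Node.1, out$Node.2),
    paste(pmin(df$Node.1, df$Node.2), pmax(df$Node.1, df$Node.2)))]
  out <- out[order(out$Node.1, out$Node.2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname read_edge_table
#' @param edges edge data.frame (or `wto_network`/`wto_consensus` object).
#' @export
write_edge_table <- function(edges, path, sep = "\t") {
  if (inherits(edges, c("wto_network", "wto_consensus")))
    edges <- as.data.frame(edges)
  out <- edges
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], function(x) signif(x, 12))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a provenance record next to an output
#'
#' Records the run configuration, seed, package version and input
#' checksums as plain text, so any output directory documents how its
#' contents were produced.
#'
#' @param path output path for the record.
#' @param config named list of run parameters.
#' @param inputs character vector of input file paths to checksum.
#' @export
write_provenance <- function(path, config, inputs = character()) {
  lines <- c(
    sprintf("package: wtonet %s", as.character(utils::packageVersion("wtonet"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    "config:",
    sprintf("  %s: %s", names(config),
            vapply(config, function(v) paste(format(v), collapse = " "),
                   character(1L))))
  if (length(inputs)) {
    sums <- tools::md5sum(inputs[file.exists(inputs)])
    lines <- c(lines, "inputs:",
               sprintf("  %s: %s", names(sums), unname(sums)))
  }
  writeLines(lines, path)
  invisible(path)
}
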