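#' Filter a network edge list
#'
#' Keeps links whose overlap magnitude reaches `min_abs_weight` and whose
#' p-value does not exceed `max_p`. Sensible defaults follow common
#' practice for overlap networks: a weight threshold of 0.5 (or an
#' empirical quantile from the fit) and the desired significance level.
#' Idempotent and monotone: raising either threshold never adds links.
#'
#' @param edges an edge data.frame (a `wto_network`/`wto_consensus` object
#'   is accepted and converted), with a weight column (`wTO_sign` or `CN`)
#'   and optionally a p-value column (`padj_sig`, `pval_sig` or
#'   `pval.fisher`).
#' @param min_abs_weight minimum \eqn{|\omega|} to keep (default 0.5).
#' @param max_p maximum p-value to keep (default 1, i.e. no p filter);
#'   applied to adjusted p-values when present.
#' @return the filtered edge data.frame.
#' @export
filter_links <- function(edges, min_abs_weight = 0.5, max_p = 1) {
  stopifnot(min_abs_weight >= 0, max_p >= 0, max_p <= 1)
  e <- graph_edges(edges)
  keep <- abs(e$weight) >= min_abs_weight & e$p <= max_p
  out <- as.data.frame(edges)
  out[keep, , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

# Column resolution shared by the graph tools: weight and p-value with the
# adjusted p preferred for filtering.
graph_edges <- function(edges) {
  if (inherits(edges, c("wto_network", "wto_consensus")))
    edges <- as.data.frame(edges)
  e <- as.data.frame(edges)
  nm <- names(e)
  wcol <- intersect(c("wTO_sign", "CN", "weight", "wTO"), nm)[1L]
  if (is.na(wcol)) stop("no weight column found (wTO_sign/CN/weight)",
                        call. = FALSE)
  pcol <- intersect(c("padj_sig", "pval_sig", "pval.fisher", "pval", "p"), nm)[1L]
  n1 <- intersect(c("Node.1", "node1"), nm)[1L]
  n2 <- intersect(c("Node.2", "node2"), nm)[1L]
  if (is.na(n1) || is.na(n2)) stop("no node columns found", call. = FALSE)
  data.frame(Node.1 = as.character(e[[n1]]), Node.2 = as.character(e[[n2]]),
             weight = e[[wcol]],
             p = if (!is.na(pcol)) e[[pcol]] else 0,
             stringsAsFactors = FALSE)
}

#' Convert an edge list to an igraph graph
#'
#' Builds an undirected graph whose edges carry the signed weight
#' (`weight_signed`), its magnitude (`weight`, used by weighted algorithms,
#' which generally require nonnegative weights), the sign (+1/-1) and the
#' p-value.
#'
#' @inheritParams filter_links
#' @param node_class optional named character vector of node classes
#'   (e.g. `"TF"` vs `"target"`), attached as a vertex attribute.
#' @return an [igraph::graph] object.
#' @export
as_wto_igraph <- function(edges, node_class = NULL) {
  e <- graph_edges(edges)
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$Node.1, to = e$Node.2,
               weight = abs(e$weight), weight_signed = e$weight,
               sign = ifelse(e$weight >= 0, 1, -1), pval = e$p),
    directed = FALSE)
  if (!is.null(node_class)) {
    cls <- node_class[igraph::V(g)$name]
    cls[is.na(cls)] <- "unknown"
    igraph::V(g)$class <- unname(cls)
  }
  g
}

#' Community detection on a wTO network
#'
#' Partitions the non-isolated nodes of an edge list with one of nine
#' community-detection algorithms, all operating on \eqn{|\omega|} as the
#' link strength (modularity-based methods require nonnegative weights;
#' the sign is retained as an edge attribute, not used for clustering).
#' Stochastic methods are made deterministic by `seed`.
#'
#' @inheritParams filter_links
#' @param method one of `"walktrap"`, `"optimal"`, `"spinglass"`,
#'   `"edge_betweenness"`, `"fast_greedy"`, `"infomap"`, `"louvain"`,
#'   `"label_prop"`, `"leading_eigen"`.
#' @param seed integer seed for stochastic algorithms.
#' @return named integer vector mapping node id to cluster id (contiguous
#'   integers starting at 0).
#' @export
cluster_nodes <- function(edges,
                          method = c("louvain", "walktrap", "optimal",
                                     "spinglass", "edge_betweenness",
                                     "fast_greedy", "infomap", "label_prop",
                                     "leading_eigen"),
                          seed = 1L) {
  method <- match.arg(method)
  g <- if (inherits(edges, "igraph")) edges else as_wto_igraph(edges)
  fun <- switch(method,
    walktrap = igraph::cluster_walktrap,
    optimal = igraph::cluster_optimal,
    spinglass = igraph::cluster_spinglass,
    edge_betweenness = igraph::cluster_edge_betweenness,
    fast_greedy = igraph::cluster_fast_greedy,
    infomap = igraph::cluster_infomap,
    louvain = igraph::cluster_louvain,
    label_prop = igraph::cluster_label_prop,
    leading_eigen = igraph::cluster_leading_eigen)
  set.seed(as.integer(seed))
  comm <- fun(g)
  m <- igraph::membership(comm)
  relabel <- match(m, sort(unique(m))) - 1L   # contiguous ids from 0
  stats::setNames(as.integer(relabel), names(m))
}

#' Export a network for downstream tools
#'
#' Writes an edge list either as TSV in the significance-table dialect or
#' as GraphML (readable by Cytoscape and igraph), carrying the signed
#' weight, magnitude, sign, p-value, and optional cluster and node-class
#' attributes. `read_graphml()` round-trips a GraphML export back to the
#' edge data.frame.
#'
#' @inheritParams as_wto_igraph
#' @param path output file path.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @param cluster optional named vector of cluster ids (see
#'   [cluster_nodes()]), attached as a vertex attribute in GraphML.
#' @return `path`, invisibly.
#' @export
export_graph <- function(edges, path, format = c("edge_tsv", "graphml"),
                         cluster = NULL, node_class = NULL) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    write_edge_table(edges, path)
    return(invisible(path))
  }
  g <- as_wto_igraph(edges, node_class = node_class)
  if (!is.null(cluster)) {
    cl <- cluster[igraph::V(g)$name]
    cl[is.na(cl)] <- -1L
    igraph::V(g)$cluster <- as.integer(cl)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname export_graph
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  out <- data.frame(Node.1 = pmin(el$from, el$to),
                    Node.2 = pmax(el$from, el$to),
                    weight = el$weight_signed,
                    pval = el$pval,
                    stringsAsFactors = FALSE)
  out[order(out$Node.1, out$Node.2), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
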