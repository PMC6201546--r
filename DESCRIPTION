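Package: wtonet
Title: Signed Weighted Topological Overlap Networks with Resampling-Based
    Link Significance and Consensus Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds signed and unsigned weighted topological overlap (wTO)
    co-expression networks from expression or abundance matrices, optionally
    restricted to a subset of nodes of interest while retaining the full
    system's adjacency in every score. Attaches per-link p-values via
    bootstrap (delta-band stability), blocked bootstrap for replicate-free
    time series, or permutation resampling, with multiple-testing
    adjustment and empirical quantile thresholds. Aggregates two or more
    networks into a sign-aware consensus network with Fisher-combined
    p-values, and post-processes edge lists with filtering, community
    detection and GraphML/TSV export. Includes generators for
    block-correlated and autoregressive synthetic expression data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    parallel,
    igraph
Suggests:
    testthat (>= 3.0.0),
    mclust,
    xml2,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
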