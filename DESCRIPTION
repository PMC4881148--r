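Package: repeatchip
Title: Reference-Free Repeat Identification and ChIP-Seq Enrichment over
    Repeat Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Graph-based clustering of unassembled genomic shotgun reads into
    repeat clusters, read-count estimation of each cluster's genome
    proportion, greedy consensus contig assembly, hierarchical repeat
    annotation against a reference repeat database, and per-cluster
    ChIP/input enrichment scoring for centromeric (CenH3-style) and
    heterochromatic (H3K9me2-style) chromatin profiling. Includes a
    synthetic-genome and read simulator with known family proportions and
    enrichment factors so the whole pipeline is testable against planted
    ground truth, plus utilities to convert genome proportions into physical
    sizes and compare cluster-based estimates with assembly-based repeat
    annotation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
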