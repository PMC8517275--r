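Package: treecoclust
Title: Tree-Constrained Co-Clustering of Binary Chromatin Accessibility Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds binary locus-by-cell-type accessibility matrices from per-cell-type
    ATAC-seq peak calls, clusters genomic loci by Louvain community detection on a
    hypergeometric similarity graph with an FDR-controlled edge threshold, and clusters
    cell types under a differentiation-tree constraint by local search over cut-vertex
    partitions that minimise a co-cluster sum-of-squares fit. The resulting co-cluster
    structure is quantified through ANOVA R-squared decompositions and a two-state
    (inaccessible/accessible) restriction, and exploited for transcription-factor motif
    enrichment with a permutation FDR cutoff and for ChIP-seq peak enrichment statistics.
    Includes a planted-partition simulator for binary matrices with block Bernoulli
    structure on a known tree, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
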