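Package: seednet
Title: Rule-Defined MicroRNA Networks, Score Overlays and Hit-Enrichment
    Statistics
Version: 0.1.0
Authors@R:
    person("Seednet", "Developers", email = "seednet@example.org",
           role = c("aut", "cre"))
Description: Builds rule-defined networks of mature microRNAs (shared-seed
    families, genomic-distance clusters of precursor loci, target-overlap
    co-regulation graphs), overlays user-supplied numeric miRNA scores on
    the nodes, and tests whether user-defined "hit" miRNAs aggregate in
    families, clusters or across edges.  Provides an upper-tail binomial
    local enrichment test, a hit-label permutation test for edge-level
    aggregation, an exact paired Wilcoxon signed-rank test for family
    export analyses, and hypergeometric target-set enrichment.  Includes a
    deterministic synthetic-annotation generator for end-to-end testing,
    GraphML/JSON/SVG export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
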