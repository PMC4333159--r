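Package: hmrkit
Title: Hypomethylated Region Calling and Cross-Tissue Methylome Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing whole-genome bisulfite methylomes between
    two cell types. Segments per-CpG methylation count data into
    hypomethylated regions (HMRs) with a two-state beta-binomial hidden
    Markov model, classifies the HMRs of two tissues into a
    tissue-specific/overlapping taxonomy (S1, C1-C5), summarises CG
    methylation by level class, genomic feature and HMR class, computes
    neighbour-CpG methylation correlation, scores motif enrichment over
    region sets, and annotates ChIP-seq peaks by methylation state. Ships
    a synthetic two-tissue methylome generator with planted regions of
    every overlap class so the whole pipeline can be exercised and
    benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
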