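Package: egrnet
Title: Enhancer-Mediated Gene Regulatory Network Inference and Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers enhancer-mediated gene regulatory networks (eGRNs) from
    paired bulk RNA-seq and chromatin accessibility cohorts. TF-peak links are
    called by an empirical false discovery rate on motif-stratified
    Pearson correlations between TF expression and peak accessibility;
    peak-gene links are called by windowed correlation with
    Benjamini-Hochberg adjustment, and the two are joined into a tripartite
    TF-peak-gene network with community detection, regulons and
    degree-preserving permutation controls. A companion evaluation framework
    scores any bipartite TF-gene network by how well it predicts differential
    expression with cross-validated random-forest regression, including
    permuted-network and random-signal controls and permutation-based TF
    importance. A seeded synthetic paired-cohort generator with a planted
    tripartite network supports end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    GenomicRanges,
    S4Vectors,
    IRanges,
    ranger,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    DESeq2,
    pROC,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
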