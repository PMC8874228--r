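Package: organoidDev
Title: Developmental Staging and Genotype Contrasts for Midbrain Organoid
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a single-cell RNA-seq analysis
    workflow for midbrain organoids: cell-level quality control and
    log-normalization, highly-variable-gene selection, PCA, mutual-nearest-
    neighbor batch correction, shared-nearest-neighbor Louvain clustering,
    cell-type assignment against a binarized marker matrix, developmental
    staging of samples by transcriptome correlation against an embryonic
    reference atlas (weeks 6-11), Wilcoxon rank-sum differential expression
    with fold-change filters, cellular composition accounting, and a minimal
    centroid-MST pseudotime with trajectory-based genotype contrasts.
    Includes a negative-binomial synthetic-data generator that emulates the
    organoid study design (WT/LRRK2-mutant conditions at two time points plus
    a weekly embryonic reference) with full ground truth, so the whole
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    igraph,
    RANN,
    irlba,
    matrixStats,
    stats,
    utils,
    methods,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    withr
Config/testthat/edition: 3
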