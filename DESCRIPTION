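Package: ldcnv
Title: Copy Number Variation Detection from Read Depth via a Local
    Distance Score
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects copy number variations (CNVs) in whole-genome
    sequencing data using a read-depth strategy. Per-base read counts are
    binned, bins overlapping reference "N" runs are removed, GC-content
    bias is calibrated by a mean-ratio correction, and the profile is
    denoised with a one-dimensional total-variation (fused lasso) model
    into piecewise-constant read-depth segments. Each segment is mapped
    into a two-dimensional feature space (depth ratio and local ratio
    difference) and assigned a local distance score: the ratio of its mean
    distance to its k nearest neighbours over the mean pairwise distance
    among those neighbours. Scores are fitted to a normal distribution and
    segments with significant right-tail p-values are reported as gains or
    losses relative to the diploid baseline. Includes a tumour-purity and
    coverage aware read-depth simulator with implanted CNV truth sets and
    a recall/precision/F1 evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    Biostrings,
    S4Vectors
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
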