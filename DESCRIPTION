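Package: kmerforest
Title: Chromatin Accessibility Classification and Variant Scoring from k-mer
    Features with Random-Forest Permutation Importance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sequence-only modelling of accessible versus inaccessible
    chromatin from k-mer count features and a random forest. Per-k-mer
    out-of-bag permutation importance (mean decrease accuracy, MDA) is
    computed from the trained ensemble and used to score the functional
    impact of single-nucleotide variants through the k k-mer windows each
    variant alters. Includes a conservation-weighted feature mode in which
    every k-mer occurrence is down-weighted by the mean per-base
    cross-species conservation frequency, a seed-deterministic synthetic
    data generator with planted motifs for end-to-end benchmarking, and
    ROC/precision-recall evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    ranger,
    Biostrings,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pROC
Config/testthat/edition: 3
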