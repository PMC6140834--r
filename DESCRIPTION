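Package: gutliveR
Title: Stage-Wise Gut-Liver Immune Resilience Analysis for Fish Feeding Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative transcriptomic and miRNAomic analysis toolkit for
    time-course feeding trials in fish, built around a four-time-point
    soybean-meal stress design in grass carp. Provides stage-wise
    negative-binomial Wald differential expression with median-of-ratios
    normalization and Benjamini-Hochberg FDR control, classification of gene
    lists against a two-level immune gene library (nine canonical immune
    processes), hypergeometric gene-set over-representation with rich factors,
    an immune-checkpoint selection rule over category-level t-tests,
    signed miRNA-mRNA correlation networks restricted to predicted target
    pairs, growth-performance and morphometry formulas, and a seeded
    synthetic-data generator with planted ground truth for end-to-end
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
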