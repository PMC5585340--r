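Package: grbtad
Title: Genomic Regulatory Blocks, Topological Domains, and Their Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for detecting conserved noncoding elements (CNEs) from
    pairwise alignment blocks, calling genomic regulatory blocks (GRBs) by
    two-state hidden Markov model segmentation of CNE density with AIC model
    selection and gap-quantile clustering, computing Hi-C directionality
    index, calling topologically associating domains (TADs) and A/B
    compartments from binned contact matrices, and quantifying the
    concordance between GRBs and TADs with permutation, Fisher and binomial
    tests. Includes a synthetic-data generator that plants known GRB, TAD,
    CTCF and repeat structure so every stage of the pipeline can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
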