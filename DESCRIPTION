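Package: sigtool
Title: Mutational Signature Discovery, Attribution and Validation
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of somatic mutational signatures in
    cancer genomes. Classifies single-base substitutions (96, 192 and
    1,536 contexts), doublet-base substitutions (78 classes) and small
    insertions/deletions (83 classes) from variant calls against a
    reference sequence; extracts signatures de novo by bootstrapped
    Kullback-Leibler non-negative matrix factorization with consensus
    clustering and by Bayesian NMF with automatic relevance
    determination, including a two-step strategy for hypermutated
    samples; attributes per-sample signature activities by constrained
    non-negative least squares with optional sparsity and biological
    allow-lists; analyses clustered (kataegis-like) substitutions;
    compares signature sets by cosine similarity and optimal matching;
    associates signature activities with age of diagnosis by robust
    regression with false-discovery-rate control; and generates fully
    ground-truthed synthetic catalogues, genomes and VCFs for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    Biostrings,
    pracma,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
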