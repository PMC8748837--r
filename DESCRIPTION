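Package: microebm
Title: Interpretable Boosted Additive Models for Cross-Study Gut
    Metagenome Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A meta-analysis pipeline for classifying colorectal cancer
    status from gut-metagenome abundance profiles (taxonomic, KEGG
    ortholog or eggNOG orthogroup namespaces). Implements a from-scratch
    explainable boosting machine (a cyclically boosted generalized
    additive model on discretized features with exact per-feature
    attributions), an FDR-controlled ANOVA front end, multi-project
    validation designs (repeated cross-validation, cross-dataset
    prediction, leave-one-project-out with and without out-of-training
    feature selection), selection- and rank-stability estimation
    (Nogueira stability, hyperbolic-weighted tau), consensus-signature
    construction with permutation significance, and a risk-ordering test
    for adenoma samples. A seeded multi-project synthetic-profile
    generator emulating batch, depth and zero-inflation structure is
    included for end-to-end exercise of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
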