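Package: npxspectrum
Title: Serum Proteomics Analysis of the Inflammatory Bowel Disease Spectrum
Version: 0.1.0
Authors@R:
    person("NPX", "Spectrum Maintainers", email = "maintainers@npxspectrum.org",
           role = c("aut", "cre"))
Description: A pipeline for targeted serum proteomics (Olink-style NPX data)
    analysis of inflammatory bowel disease heterogeneity: preprocessing of
    long-format NPX tables (QC exclusion, assay exclusion, below-LOD filtering,
    batch adjustment), univariate differential screening (Welch t-tests,
    Benjamini-Hochberg FDR, fold-change thresholds, covariate-adjusted models,
    PCA overview with rank-based group tests), a from-scratch SCAD plus ridge
    penalized logistic regression solver with nested cross-validation, CD
    versus UC probability scores that place disease subgroups along an
    ileal-colonic continuum, a down-sampled repeated cross-validation
    classifier benchmark, and a synthetic-cohort generator with ground truth
    so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse,
    withr
Config/testthat/edition: 3
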