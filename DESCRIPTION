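Package: germpred
Title: Genomic Prediction for Germplasm Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Whole-genome regression for predicting the genetic merit of
    accessions held in germplasm collections from historical multi-trial
    phenotype records and genome-wide marker data. Implements G-BLUP with
    an efficient eigendecomposition-based REML, Bayes B and Bayesian LASSO
    Gibbs samplers, a per-marker-standardized genomic relationship matrix,
    fixed-effect phenotype adjustment for trial and maturity-group effects,
    four cross-validation schemes over trial, state, or genetic-cluster
    groupings with strict accession-level leakage control, bootstrap
    confidence intervals for predictive ability, selection-enrichment
    statistics, and a synthetic germplasm-collection generator emulating a
    structured, fully inbred diversity panel.
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
    readr,
    stats,
    utils,
    ggplot2,
    generics,
    lme4,
    vcfR,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
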