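Package: wintergp
Title: Genomic Prediction of Winter Survival in Structured Plant Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic selection of winter survival in structured
    perennial-grass breeding populations such as lowland switchgrass. The
    package covers the full analysis path: simulation of diverged
    subpopulations with half-sib trial phenotypes and allelic read depths,
    marker quality control (missingness, minor allele frequency,
    Hardy-Weinberg filtering, mean imputation), genomic relationship and
    identity-by-state matrices, principal components, LD decay and MAF
    spectra, REML estimation of trial variance components and family BLUPs,
    GBLUP with genomic heritability and k-fold cross-validation, a
    mixed-population Matern-kernel extension of GBLUP for heterogeneous
    panels, Bayesian whole-genome regression (BayesA, BayesB, Bayesian
    lasso) via Gibbs sampling, ploidy inference from allelic read-depth
    fractions, and geographic validation of predicted breeding values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
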