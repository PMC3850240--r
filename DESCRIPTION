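Package: enetgwas
Title: Lasso and Elastic-Net Variable Selection for GWAS with
    LD-Structured Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Benchmarks penalized-regression variable selection on
    genome-wide SNP data. Provides a linkage-disequilibrium-structured
    genotype and phenotype simulator with known causal SNP sets, an
    elastic-net cyclic coordinate-descent solver over a decreasing lambda
    path with penalty factors for unpenalized covariates, k-fold
    cross-validation with the minimum-MSE and one-standard-error tuning
    rules, single-marker regression with Bonferroni and local false
    discovery rate selection, spectral eigenvector covariates for
    population-structure correction, quality-control filters for 0/1/2
    genotype matrices, and an evaluation harness that scores selections
    against the simulated causal truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    splines,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
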