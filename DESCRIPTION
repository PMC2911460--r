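Package: fadex
Title: Factor-Adjusted Analysis of Heterogeneity in Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fits a latent factor model to the covariate-residualized part of a
    gene expression matrix by maximum likelihood (EM), selects the number of
    factors by minimizing a variance-inflation criterion for the false
    discovery count, applies a VARIMAX rotation, and subtracts the estimated
    common-factor component to obtain factor-adjusted expression data for
    differential expression analysis. Estimated factors are interpreted
    against external sample covariates and gene features by analysis of
    variance, and gene lists are characterized by exact hypergeometric
    over-representation tests. Includes generators for fully specified
    synthetic heterogeneity scenarios so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
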