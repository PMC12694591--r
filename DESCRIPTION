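Package: caft
Title: Compositional Accelerated Failure Time Models for Microbiome
    Differential Abundance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Differential abundance analysis for sparse microbiome count
    tables using a compositional accelerated failure time (CAFT) model.
    Zero counts are treated as right-censored observations of the negative
    log relative abundance, with the log library size as the censoring
    time, so no pseudocounts are needed. Per-taxon regression coefficients
    are estimated by minimizing a convex Gehan-type rank objective, taxa
    are tested against a spatial-median compositional reference via
    restricted score tests with a rank-based variance estimator, and the
    false discovery rate is controlled by Benjamini-Hochberg. Includes a
    sparse community simulator with multiplicative taxon-specific bias
    factors and multiplicative covariate effects for evaluating operating
    characteristics, readers for TSV/CSV and BIOM count tables, and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    survival,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    withr
Config/testthat/edition: 3
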