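Package: famimpute
Title: Mendelian Imputation of Parental Genotypes and Family-Based
    Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Family-based genetic association toolkit. Imputes missing
    parental genotypes from genotyped relatives using Mendelian laws and
    identity-by-descent (IBD) sharing between siblings, infers sibling IBD
    segments with a hidden Markov model, and estimates direct genetic
    effects, non-transmitted coefficients and sibling indirect effects by
    generalized least squares under a family random-effect linear mixed
    model. Includes polygenic-index (PGI) analysis with an adjustment for
    imputation bias under assortative mating, a moment-based estimator of
    genome-wide correlations between effect classes that corrects for
    sampling error, closed-form efficiency and bias formulas for
    diagnostics, and a forward-in-time nuclear-family simulator used as
    the universal test-data source.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    lme4,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
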