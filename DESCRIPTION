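Package: xpopexpr
Title: Cross-Population Genetic Architecture of Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the genetic architecture of gene
    expression transfers across ancestrally diverse populations.
    Implements cis-eQTL mapping with genotype-PC and hidden-factor
    covariates, Storey pi1 replication statistics, cis-window
    heritability and bivariate genetic correlation by average-information
    REML with positive-definite bending, per-gene elastic-net expression
    prediction with nested cross-validation, cross-population model
    transfer with allele harmonization, and Weir-Cockerham FST analysis
    of transfer failure. Includes a multi-population synthetic cohort
    generator (Balding-Nichols allele-frequency divergence, sparse cis
    architectures, tunable heritability and between-population effect
    correlation) and a configuration-driven pipeline that runs the whole
    analysis end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    glmnet,
    ggplot2,
    generics,
    jsonlite,
    readr,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
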