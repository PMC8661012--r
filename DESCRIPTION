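Package: bimr
Title: Bi-Directional One-Sample Mendelian Randomization Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for one-sample, bi-directional Mendelian randomization
    studies of a continuous exposure and a binary outcome (the motivating
    application is platelet count and hypertension). Provides a synthetic
    cohort generator with known causal structure, genotype quality control
    (individual missingness, SNP call rate, Hardy-Weinberg exact test,
    sliding-window LD pruning), covariate-adjusted per-SNP association scans
    with instrument selection and F-statistic screening, and the
    inverse-variance-weighted, MR-Egger, simple-median and weighted-median
    causal estimators, together with a simulation-study harness that
    measures bias, coverage and type-I error of the estimators under
    registered scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    knitr
Config/testthat/edition: 3
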