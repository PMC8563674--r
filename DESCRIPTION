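Package: maternalmr
Title: Maternal-Effect Mendelian Randomisation with Fetal Genotype Adjustment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-sample Mendelian randomisation of maternal exposures on
    offspring outcomes using maternal genetic effects decomposed from fetal
    effects with the weighted linear model (WLM). Provides GWAS
    summary-statistic harmonisation to the exposure-increasing allele,
    Wald-ratio and inverse-variance-weighted pooling, MR-Egger,
    weighted-median and radial-MR sensitivity estimators, Cochran's Q and
    I-squared heterogeneity, leave-one-out and multivariable MR,
    individual-level mother-child conditional analysis, and a seeded
    synthetic mother-child population generator with known ground truth for
    method validation. All user-facing functions take data frames and return
    tibbles so analyses compose with the pipe.
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
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
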