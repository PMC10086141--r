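Package: mrmediation
Title: Two-Sample Mendelian Randomization and Mediation Analysis with
    Multivariable MR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization (MR) workflow for
    GWAS summary statistics: instrument selection (genome-wide significance
    filtering, greedy LD clumping, instrument-strength statistics),
    effect-allele harmonization with frequency-based resolution of palindromic
    variants, a suite of causal estimators (inverse-variance-weighted under
    fixed and multiplicative-random-effects models, MR-Egger, weighted median,
    weighted mode), diagnostics (Cochran's Q, I2-GX, Egger intercept,
    MR-PRESSO outlier detection, leave-one-out), multivariable MR, and a
    two-step mediation decomposition with the Sobel test and proportion
    mediated. Includes a seeded generator of synthetic two-sample GWAS summary
    statistics with known causal, pleiotropic, and mediation structure so
    every stage is testable without consortium data.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
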