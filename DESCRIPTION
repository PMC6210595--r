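Package: presvar
Title: Interrupted Time Series and Variation Analysis of Practice-Level Prescribing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing monthly general-practice prescribing around a
    drug-safety communication. Reads NHS-style practice prescribing and
    characteristics tables, constructs a drug's percentage share of its class,
    applies standard practice exclusion rules, quantifies between-practice
    variation (systematic component of variation on percentile-trimmed panels,
    standardized and rolling prescribing ratios, exact rank-sum comparison),
    fits a multilevel segmented regression with practice random effects and
    optional AR(2) residual correlation, classifies practices by their
    post-communication level and slope changes using BLUPs with conditional
    standard errors, and models practice characteristics as predictors of a
    prescribing decrease. Includes a synthetic panel generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    lme4,
    nlme,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
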