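Package: cocktailr
Title: Simulation and Individual-Differences Analysis of Cocktail-Party Listening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates cohorts of young normal-hearing listeners performing a
    psychoacoustic and cognitive test battery (matrix-sentence identification
    with competing talkers, intensity discrimination in quiet and under
    backward masking via 3-down-1-up adaptive staircases, binaural
    temporal-fine-structure sensitivity, a visual flanker task, a sentence
    span task, audiograms and the SSQ questionnaire), scores every task with
    the standard transforms and screening rules, and analyses the
    individual-differences structure: z-standardised OLS regression with
    outlier and collinearity diagnostics, dominance analysis (general
    dominance weights), Lasso subset selection with k-fold cross-validation,
    age-controlled partial correlations, absolute-agreement intraclass
    correlations, and noncentral-t power analysis for regression
    coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
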