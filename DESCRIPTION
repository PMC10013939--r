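Package: hbsr
Title: Health Behavior Stroke Risk Scoring and Case-Control Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the Health Behavior Stroke Risk (HBSR) score, a 0-10
    composite of five lifestyle factors (smoking, body-mass index, physical
    exercise, diet, alcohol use) graded low/moderate/high from questionnaire
    answers, together with the full case-control comparison pipeline used in
    young-stroke epidemiology: complete-case prevalence tables stratified by
    age band, pooled two-proportion z-tests with Bonferroni correction, crude
    and covariate-adjusted odds ratios from an internally implemented
    iteratively reweighted least squares logistic fit, and mean-score
    comparisons. A seedable Gaussian-copula synthetic cohort generator
    reproduces published category marginals and covariate mixes so every
    pipeline stage is testable without individual-level survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    broom
Config/testthat/edition: 3
RoxygenNote: 7.3.3
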