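Package: emultrial
Title: Target Trial Emulation for Clustered Educational Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Emulates a pragmatic target trial of special educational needs
    (SEN) provision on health and attainment outcomes in clustered
    pupil-level cohorts. Provides a synthetic clustered-cohort generator
    with an exact potential-outcomes oracle, derivation of hospitalisation,
    absence and attainment outcomes, pairwise propensity-score models with
    positivity diagnostics, inverse-probability weighting, g-computation
    and augmented IPW estimation of average treatment effects (ATE) and
    effects on the treated (ATT), and cluster-bootstrap interval
    estimation. Missing confounders are handled by the missing-covariate
    indicator method.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    utils,
    MASS,
    glmnet,
    sandwich,
    ggplot2,
    generics,
    jsonlite,
    readr
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
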