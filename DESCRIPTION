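Package: resilgap
Title: Academic Resilience Classification and Explanatory Modelling for
    Longitudinal School Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies academically resilient children in longitudinal
    cohort data: stratifies children into four school-entry percentile
    groups on a developmental score, derives stratum-specific predicted
    Grade-3 achievement scores from baseline regressions, classifies
    vulnerable children as resilient or ongoing-vulnerable by comparing
    actual with predicted achievement, screens explanatory child,
    parenting and school factors with chi-square tests and one-way
    ANOVAs, and fits a covariate-adjusted path model of resilient group
    membership over multiply-imputed datasets with Rubin's-rules
    pooling and latent-response standardized estimates. Ships a
    synthetic-cohort generator with correlated mixed-type covariates
    and calibrated missing-at-random missingness so the full pipeline
    is testable without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
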