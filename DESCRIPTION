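Package: pdmedalg
Title: Medication-Based Identification of Parkinson's Disease in Longitudinal EHR Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based medication algorithm for identifying Parkinson's
    disease (PD) cases in longitudinal electronic-health-record data:
    inclusion screening on antiparkinsonian medication (APM) purchases,
    fourteen exclusion criteria targeting alternative indications and
    atypical parkinsonism, probable/possible diagnostic-certainty tiers, and
    index-date rules. Ships validation metrics (sensitivity/specificity with
    Wilson and exact binomial confidence intervals), incidence and prevalence
    estimation with exact Poisson intervals, direct age standardization to
    the WHO world standard population, annual-percent-change trend regression
    with quasi-Poisson overdispersion handling, matched case-control
    construction for pre-diagnostic diagnosis prevalence with chi-squared
    tests and false-discovery-rate correction, and a seeded synthetic-EHR
    generator with per-criterion confounder archetypes and known ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
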