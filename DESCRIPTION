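Package: cohortsens
Title: Sensitivity of Claims-Based Case-Control Associations to Control
    Definitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds case-control cohorts for type 2 diabetes from
    administrative claims tables with rule-based (eMERGE-style) phenotyping,
    applies four permutations of the control eligibility rules that differ
    only in their glucose/HbA1c laboratory requirement, matches controls to
    cases exactly on age and sex, and measures the depression-diabetes
    association as a bootstrap distribution of Fisher's exact odds ratios.
    Includes a seeded synthetic claims generator with a latent-truth table
    (configurable comorbidity odds ratio, age-increasing lab-testing
    intensity, informative missingness of returned lab values) so the whole
    pipeline can be exercised and calibrated without access to proprietary
    claims data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    stats,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
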