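Package: smaclaims
Title: Adherence, Persistence and Cost Analysis for SMA Pharmacy Claims
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for retrospective administrative-claims
    analyses of oral disease-modifying therapy in spinal muscular atrophy
    (SMA): cohort selection with an auditable exclusion funnel, claims-based
    SMA type classification via a configurable rule table, proportion of
    days covered (PDC) adherence with days-of-supply stacking, gap- and
    switch-based treatment persistence with a product-limit (Kaplan-Meier)
    survival estimator, and per-patient per-year all-cause cost
    summarization with treatment-cost exclusion and inflation adjustment.
    Includes a synthetic claims generator with known ground truth so every
    stage is testable without access to a licensed claims database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
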