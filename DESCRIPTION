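Package: dosepair
Title: Dosage Adjustments in Co-Medication Pairs from Inpatient Prescriptions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for estimating how co-medications associate with
    dosage adjustments of an index drug in timestamped inpatient prescription
    data. Computes prescribed average daily doses from dosing regimens, builds
    monotherapy and concomitant treatment episodes by interval algebra, fits
    hierarchical Bayesian binomial logistic regressions per index drug with
    89% highest-density intervals and a region-of-practical-equivalence
    decision rule, runs propensity-matched post-hoc association analyses
    (discontinuation, 30-day mortality, 30-day readmission, length of stay,
    diagnosis and blood-test enrichment), and annotates significant pairs with
    drug-drug-interaction evidence and shared cytochrome/transporter activity.
    Includes a synthetic electronic-health-record cohort generator with
    planted effects so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    stats,
    utils,
    tools,
    survival,
    rjags,
    coda,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
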