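Package: ddci
Title: Drug Derived Complexity Index from Prescription Claims
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Drug Derived Complexity Index (DDCI), a
    prescription-based comorbidity and clinical-complexity score for
    administrative claims cohorts. Provides a rule engine that converts
    baseline-year ATC-coded dispensing records into 19 drug-class exposure
    flags, an integer scorer with risk-class binning, re-derivation of the
    integer weights from cohort data via Cox proportional-hazards
    regression with a divide-and-round rule, a bundled Charlson
    Comorbidity Index (Deyo ICD-9-CM mapping) for comparison, and an
    evaluation battery covering Kaplan-Meier curves, class-wise hazard
    ratios, Harrell's survival C-index, continuous Net Reclassification
    Improvement, and Poisson incidence-rate-ratio models for hospital
    readmissions. A synthetic claims-cohort simulator reproduces the
    statistical structure the pipeline assumes so that every stage is
    testable without access to real health databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
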