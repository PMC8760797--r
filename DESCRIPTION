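Package: sepsiscriteria
Title: Rule-Based Sepsis Phenotyping and Temporal Agreement with Expert Labels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects Sepsis-1/2 and Sepsis-3 onset from ICU electronic health
    record event streams by rule-based clinical criteria (suspicion-of-infection
    order pairing, SIRS point determination, rolling 24-hour SOFA scoring),
    processes daily expert working-diagnosis labels from a bedside
    questionnaire survey, and quantifies temporal and dichotomous agreement
    between the two with chance-corrected coefficients (Krippendorff's alpha,
    prevalence-adjusted bias-adjusted kappa) and confusion-matrix test
    performance. Includes a synthetic ICU cohort generator that emulates the
    statistical structure of such a survey so the whole pipeline is testable
    without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
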