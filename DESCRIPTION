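Package: dmcascade
Title: Inpatient Cascade of Diabetes Care from Event-Level EHR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constructs an inpatient-adapted cascade of type 2 diabetes care
    from event-level electronic health record extracts. Patients are staged as
    diagnosed (ICD-10 E11.xx on the admission problem list, after excluding
    gestational and type 1 diabetes), linked to care (anti-diabetes medication
    prescribed within 90 days of discharge), and glycemic-controlled
    (follow-up HbA1c at or below an individualized target of 7.0, 7.5, 8.0 or
    8.5 percent determined by age band and complication/cardiovascular
    status). Provides the three inpatient glycemic-care markers, stratified
    cascade tables with the field's denominator conventions, pooled
    two-proportion equality tests between cascade stages, a seeded synthetic
    EHR cohort generator, and a packaged fixture of published aggregate counts
    for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
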