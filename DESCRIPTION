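Package: le8af
Title: Life's Essential 8 Cardiovascular Health and Prognosis in Atrial
    Fibrillation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study the prognostic value of the American Heart
    Association's Life's Essential 8 (LE8) cardiovascular-health score in
    people with atrial fibrillation over a 10-year horizon: a calibrated
    synthetic-cohort generator, LE8 component and composite scoring with
    an adapted nine-item diet metric, derivation of all-cause mortality
    and major-adverse-cardiovascular-event endpoints from ICD-10-coded
    records, crude event-rate tables and Kaplan-Meier curves,
    penalised-spline and quartile Cox proportional-hazards models with
    moderation tests, landmark and competing-risk sensitivity analyses,
    and scenario-based population attributable and potential impact
    fractions with bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    survival,
    tools,
    utils
Suggests:
    cmprsk,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
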