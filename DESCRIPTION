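Package: icualarms
Title: Rule-Based Actionability Annotation of ICU Patient-Monitoring Alarms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates intensive-care patient-monitoring alarms as actionable
    or nonactionable by linking each alarm to respiratory and medication
    management interventions documented in patient data management system
    (PDMS) style records within defined post-alarm time windows. Implements a
    deterministic eight-rule engine over five physiological alarm conditions,
    leveled airway-device and respiratory-support-therapy mappings, a
    ventilation-parameter compatibility table, medication administration
    change detection with dose-per-time rate comparison, preprocessing
    (stay linkage, range filtering, planned-intervention exclusion), and a
    seeded synthetic ICU data generator with documentation-error injection
    (missing airway-device removals, standby mis-documentation, five-minute
    timestamp rounding) so the whole method is testable without hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
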