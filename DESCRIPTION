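Package: edsepsis
Title: Automated Emergency-Department Sepsis Alerting and Its Diagnostic-Accuracy Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A rule-based screening engine for sepsis in the emergency
    department: time-stamped vital-sign and laboratory streams are scanned
    asynchronously and a sepsis alert fires once two or more SIRS
    (systemic inflammatory response syndrome) criteria plus at least one
    sign of shock (hypotension or elevated lactate) have been fulfilled,
    possibly at different time points, with repeat activation as further
    criteria accrue. Companion tools evaluate the alerts against
    chart-review labels under a sampled-negatives verification design
    (positive and estimated negative predictive values with exact
    Clopper-Pearson intervals, infection and condition category tables,
    disposition tables, Cohen's kappa), and a seeded synthetic
    emergency-department cohort generator produces labelled encounters
    with configurable alert prevalence so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
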