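Package: wardflow
Title: Atypical Intrahospital Ward Transfers and Patient Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A data-driven pipeline for characterising intrahospital patient
    movement from ward-entry event logs. Ward speciality profiles are derived
    from deposited treatment function codes via the Herfindahl-Hirschman
    concentration index and its equivalent market size; every ward-to-ward
    move is classified as an atypical (no shared specialities), regular, or
    site (cross-site) transfer; and the association of each transfer type
    with length of stay (gamma log-link GLM with average marginal effects),
    30-day emergency readmission and in-hospital mortality (logistic models)
    is estimated with patient-clustered sandwich standard errors. A synthetic
    multi-site EHR cohort generator with planted transfer structure makes the
    whole pipeline testable without access to closed hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
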