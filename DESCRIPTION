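Package: ozmediate
Title: Mediation of Prenatal Ozone Effects on Term Birth Outcomes by
    Gestational Hypertension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for birth-cohort analyses of prenatal
    ozone exposure, term low birth weight and small-for-gestational-age:
    eligibility cascades with exclusive exclusion accounting, outcome
    derivation against a growth reference, whole-pregnancy exposure
    averaging, per-IQR effect estimation from logistic and Cox models
    under the rare-outcome OR-as-RR convention, composite analysis
    weights (raking calibration times inverse-probability-of-selection,
    truncated and mean-one normalized), and two families of mediation
    decomposition: a four-step Sobel/Buis analysis and counterfactual
    natural direct/indirect effects on the odds-ratio scale with optional
    exposure-mediator interaction and bias-corrected bootstrap intervals.
    A synthetic-cohort generator with derivable ground-truth effects makes
    every stage testable without registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
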