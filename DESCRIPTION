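Package: ehapi
Title: Hospital-Acquired Pressure Injury Phenotyping from Electronic Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A configurable rule engine for labeling hospital stays with
    hospital-acquired pressure injury (HAPI) status from electronic health
    record tables in the MIMIC-III schema. Implements the EHAPI case
    definition together with three earlier MIMIC-III definitions (CANTRIP,
    Cramer, Sotoodeh) as policies over eight decision dimensions, pressure
    injury stage encodings covering deep tissue injury and unstageable
    wounds, keyword scanning of clinical notes with window-based negation
    detection, source-congruence (UpSet-style) analytics across chart
    events, notes, diagnosis and procedure codes, and a leakage-safe
    case-control classification benchmark with duration-matched control
    event timestamps. Ships a synthetic MIMIC-schema cohort generator with
    exact per-definition ground-truth bookkeeping for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    xgboost,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
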