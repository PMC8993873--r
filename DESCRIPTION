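Package: ehrbias
Title: Quantifying Ascertainment Bias in Electronic Health Record Cohort Design
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates electronic health records with risk-dependent data
    completeness and delayed recording of prevalent disease, constructs a
    longitudinal primary-care cohort and a complete-data convenience sample
    from the same synthetic record, recovers vital signs from free-text notes
    with a rule-based labeler, computes the CHARGE-AF and Pooled Cohort
    Equations risk scores, and evaluates discrimination (IPCW concordance,
    hazard ratio per SD) and calibration (Greenwood-Nam-D'Agostino test,
    integrated calibration index, calibration slope) to quantify how sampling
    design propagates ascertainment bias into survival model performance.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    splines,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
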