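Package: sareclass
Title: Risk Reclassification Analysis for Sickness-Absence Prognostic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the added predictive value of a new predictor over an
    established binary-outcome prognostic model using reclassification tables,
    event and nonevent Net Reclassification Indices (NRIe, NRIne), the
    integrated discrimination improvement (IDI), the discrimination slope, and
    Hosmer-Lemeshow calibration testing.  Includes occupational-cohort domain
    tools (sickness-absence episode merging and aggregation from register
    data, outcome labelling), a seeded synthetic-cohort generator calibrated
    to a published office-worker study of fatigue and sickness absence, an
    end-to-end study pipeline, and embedded reference reclassification tables
    for exact verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
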