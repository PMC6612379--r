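Package: posturostat
Title: Plantar Pressure Weight Distribution and Multiple-Response Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes pressure-platform recordings of quiet standing into
    lateral and anteroposterior body weight distribution indices (OLWD, APWD),
    classifies per-condition shifts against a rest baseline, and tests the
    association between occlusal condition and weight-distribution shift with
    the modified and corrected chi-squared test for multiple-response
    contingency tables (after Decady and Thomas), visualised by correspondence
    analysis. Includes a synthetic posturography generator emulating a
    resistive pressure mat, so the full pipeline is testable without an
    instrument.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    data.table,
    EBImage
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
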