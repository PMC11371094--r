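Package: mmstage
Title: Rule-Based Extraction of Multiple Myeloma Stage from Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A rule-based natural language processing pipeline that extracts
    multiple myeloma (MM) stage mentions (R-ISS, ISS, Durie-Salmon, or stage
    with no documented system) from free-text clinical notes, and rolls
    snippet-level stage labels up to a single per-system patient-level stage
    assignment at treatment initiation. Includes candidate-snippet windowing,
    span labeling with value and system normalization, context suppression of
    non-myeloma stage mentions (for example chronic kidney disease stage and
    double-strength antibiotic abbreviations), proximity-based association of
    stage values with staging systems, per-system contingency-table evaluation
    (precision, recall, F1), and a seeded synthetic note and corpus generator
    with internally consistent gold annotations so the full stack is testable
    without access to restricted electronic health record data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    rlang,
    tibble,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
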