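Package: phalanx
Title: Pediatric Phalangeal Length Ratio Reference Ranges and Turner
    Syndrome Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for radiogrammetry of hand bones on pediatric bone-age
    radiographs. Builds trimmed, age-stratified normative reference ranges
    for metacarpal and middle-phalanx length ratios (4:3 MC, 5:3 MC,
    5:3 MP), screens subjects for the metacarpal sign and brachydactyly
    type A3 by age-matched z-scores, and evaluates threshold-based
    classification with ROC/Youden analysis. Includes a calibrated
    synthetic-cohort generator (log-normal bone-length model with a
    shared-denominator noise structure and a two-component mixture for the
    Turner syndrome 4:3 MC distribution) so the full pipeline is testable
    without radiographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
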