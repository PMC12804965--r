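Package: i1metrics
Title: Image-Level Behavioral Metrics for Two-Alternative Forced-Choice Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-detection analysis of image-level behavior in binary
    (two-alternative forced-choice) visual categorization tasks. Computes
    per-image d-prime vectors (i1) and their category-mean-normalized form
    (i1n), cross-validated lapse-rate estimates and lapse-corrected accuracy,
    split-half noise-ceiling-corrected correlations between observer pools,
    and bootstrap confidence intervals for condition effects such as face
    inversion and contrast reversal. Includes a linear-readout "model
    observer" that turns per-image feature representations into the same
    image-level metrics, and a synthetic-data module that generates stimulus
    metadata, simulated observer pools, and two-class feature sets with the
    statistical structure the analysis assumes, so the whole pipeline is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
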