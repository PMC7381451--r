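Package: morphsens
Title: Psychometric Sensitivity to Morph-Diluted Facial Expressions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Measures an observer's sensitivity to morph-diluted facial
    expressions from two-interval forced-choice (2IFC) discrimination data.
    Fits logistic psychometric functions by maximum likelihood with fixed
    guess and lapse rates, extracts the 75%-correct dilution threshold, and
    tests whether two conditions differ within a single observer using a
    parametric-bootstrap likelihood-ratio comparison of one shared versus
    two separate psychometric functions. A synthetic-observer simulator
    implements method-of-constant-stimuli trial schedules so the whole
    pipeline can be exercised, calibrated and power-analysed without
    behavioral data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    readr,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
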