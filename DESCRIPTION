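Package: ppgheat
Title: Time-Domain Photoplethysmogram Analysis for Heat-Stress Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing exercise-induced heat stress from short
    fingertip photoplethysmogram (PPG) recordings. Implements the full
    time-domain analysis chain: zero-phase Butterworth bandpass filtering,
    the three-point second derivative (acceleration plethysmogram, APG),
    a/b-wave fiducial handling, fourteen energy/amplitude/slope features
    plus the RMSSD heart-rate-variability index, a Mann-Whitney separability
    screen with Holm-Bonferroni correction, and leave-one-out classification
    with Mahalanobis, LDA, QDA and linear-SVM classifiers. A synthetic
    paired-cohort generator with ground-truth fiducials makes every stage
    testable without access to restricted clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
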