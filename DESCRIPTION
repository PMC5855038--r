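Package: ecgmatch
Title: Human Identification from Personalized 12-Lead ECG Beat Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for closed-set human identification from personalized
    12-lead electrocardiogram beat patterns. Implements pre-processing of
    500 ms averaged PQRST patterns (detrending, aVR reference alignment,
    QRS extraction, Bazett QT correction), three template-comparison
    feature families (max-lag and zero-lag cross-correlation, peak-to-peak
    amplitude ratio, and a binary time-amplitude pattern-matching
    transform yielding time- and amplitude-equality measures), a
    similarity-index decision rule with forward-stepwise training of
    feature-by-lead identification models, evaluation of identification
    accuracy as a function of reference-database size, and a seeded
    synthetic two-session cohort generator for method development.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
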