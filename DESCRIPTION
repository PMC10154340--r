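Package: tapsync
Title: Analysis of Pacing-Continuation Finger-Tapping Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing sensorimotor-synchronization
    finger-tapping sessions in the synchronization/syncopation-continuation
    paradigm. Simulates tap-event sessions under blocked or alternating trial
    orderings, computes (virtual) asynchrony and inter-response-interval
    statistics, applies IQR outlier rejection and bootstrap balancing, fits
    multiple-regression models with Tukey HSD contrasts and noncentral-F
    post-hoc power, estimates trend turning points from the second derivative
    of cubic-spline growth-curve fits, and quantifies the causal effect of
    study design by difference-in-differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
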