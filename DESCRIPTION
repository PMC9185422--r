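Package: steerecg
Title: Reliability Analysis of Steering-Wheel Electrocardiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing how much of an in-vehicle, steering-wheel
    electrocardiogram (ECG) is reliable enough for heart-rate monitoring.
    Provides a synthetic dual-channel driving-session generator with known
    R-wave ground truth, a bank of classical R-peak detectors (Pan-Tompkins,
    squared-derivative, Shannon-energy envelope), STAPLE
    expectation-maximization fusion of detector annotations into a consensus
    with per-detector sensitivity and specificity estimates, periodogram-based
    harmonic signal-to-noise ratio of the wheel channel against a chest
    reference, rule-based classification of reliable recording time, and
    scenario-level study summaries. All user-facing functions take and return
    tibbles so analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    stats,
    withr,
    yaml,
    readr,
    digest,
    cli
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    openssl
Config/testthat/edition: 3
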