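Package: epochcounts
Title: Epoch-Based Activity Counts from Raw Accelerometer Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts raw tri-axial (or uni-axial) accelerometer recordings in
    gravitational units into the epoch-based activity counts produced by
    ActiGraph's ActiLife and CentrePoint software (wGT3X-BT, GT9X and
    CentrePoint Insight Watch device generations). Implements the full
    processing chain: resampling of any admissible input rate to 30 Hz
    (including the x3 up-sampling recursion with first-order low-pass and the
    CentrePoint Insight Watch pre-resampling path), the 7th-order IIR
    band-pass filter with steady-state step-response initialization,
    rescaling, rectification, deadband-and-saturation thresholding,
    decimation to 10 Hz by non-overlapping three-sample averages, and
    per-epoch summation. Ships a synthetic-signal validation harness that
    cross-checks the vectorized pipeline against an independent scalar-loop
    reference implementation on seeded Gaussian white noise, plus
    frequency-response characterization of the band-pass filter and a
    command-line interface.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
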