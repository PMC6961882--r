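Package: vorsac
Title: Quantitative Analysis of Video Head Impulse Test Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing pipeline for the video head impulse test
    (vHIT). Detects head impulses from angular velocity traces using
    Laplacian-of-Gaussian gradient estimation and a tangent-intercept onset
    rule, separates compensatory saccades from the vestibulo-ocular reflex
    (VOR) slow phase by fitting a dual-Gaussian saccade waveform that
    minimizes a high-pass-filtered least-squares cost, computes the
    position-ratio VOR gain and pre-saccadic visual position error,
    sequences and classifies saccades (covert/overt,
    compensatory/anti-compensatory), and aggregates per-condition summary
    tables. Includes a seeded synthetic-trial generator with ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
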