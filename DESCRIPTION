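Package: lrtceeg
Title: Single-Trial Long-Range Temporal Correlation Analysis of Broadband EEG
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Sliding-window detrended fluctuation analysis (DFA) of broadband
    EEG for tracking instantaneous changes in long-range temporal correlations
    (LRTC) during movement and motor imagery. Provides causal 2 s Hanning
    windows at 100 ms steps, Hurst exponent time courses with exponential
    smoothing, a three-stage LRTC validation cascade (sample-shuffle surrogate
    test, ARMA versus ARFIMA discrimination by AIC with fractional
    differencing, and maximum-likelihood DFA linearity validation), stitched
    alpha-band amplitude-envelope LRTC on long timescales, group time-course
    statistics with normality-gated test selection, and per-window linear
    discriminant classification with exact binomial chance thresholds. A
    synthetic EEG generator with exact fractional Gaussian noise (circulant
    embedding) and known ground-truth Hurst dynamics makes every stage
    testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
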