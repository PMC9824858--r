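Package: stemecho
Title: Primary Ultrasonic Echo Detection in Plant Stems by Hybrid
    Differential AIC
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for locating the primary ultrasonic echo in
    radio-frequency A-scans of plant stems. Implements the classical
    Akaike Information Criterion (AIC) change-point picker and a hybrid
    differential AIC picker that recovers the echo onset when the global
    AIC minimum sits at the burst/noise junction instead of the echo.
    Includes a seeded simulator of three-segment pulse-echo A-scans with
    ground truth, pulse-echo velocity and stem moisture-content physics
    for water-immersion experiments, correlation analytics for tracking
    echo position against environmental covariates, and a command-line
    interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
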