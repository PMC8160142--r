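Package: phosread
Title: Gaze-Contingent Simulation of Phosphene Vision for Reading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates reading through a visual prosthesis with 2000
    eccentricity-weighted phosphenes. Provides tangent-plane screen
    geometry, camera steering under full-gaze versus head-only modes,
    blue-noise generation of center-weighted phosphene fields,
    logMAR-calibrated three-line sentence stimuli in the MNREAD style,
    retinally stabilized Gaussian-phosphene rendering, a synthetic
    observer that runs the full mini-block trial protocol, and the
    psychometric analysis of the resulting session logs (reading
    accuracy and speed, median with 16/84 percentile summaries,
    logistic equivalent acuity, and nonparametric tests with exact
    small-sample enumeration).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
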