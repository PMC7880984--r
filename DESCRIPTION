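Package: saccfit
Title: Model-Based Saccade Kinematics and Main-Sequence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for oculomotor performance analysis from gaze recordings.
    Saccades are detected on velocity-thresholded gaze traces, each trajectory
    is fitted with a Hill-form sigmoid so that amplitude, duration and peak
    velocity are obtained analytically with sub-sample resolution and remain
    robust down to ~50 Hz sampling, and the amplitude/peak-velocity main
    sequence is characterized with nine literature models. Bootstrap machinery
    quantifies goodness-of-fit, repeatability (symmetric MAPE between fitted
    curves), amplitude-range generalization, minimum sample size (Hotelling
    T-squared stability) and robustness to downsampling. A synthetic gaze
    generator with known ground truth supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
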