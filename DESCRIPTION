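Package: perisim
Title: Desk-Scale Simulation of Virtual-Reality Static Perimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulation framework for head-mounted static perimetry: the
    Humphrey 30-2 test grid and its angular geometry on a virtual bowl,
    gaze-contingent stimulus placement, perimetric decibel/apostilb
    photometry, a bisection thresholding staircase with central seeding,
    frequency-of-seeing simulated observers with false-positive and
    false-negative rates and gaze wander, complete simulated exams with
    grayscale-map rendering, and the sector-based comparison statistics
    (regional means, Pearson correlation with strength classes, reliability
    filtering, paired t-tests) used to compare two perimetric devices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tidyr,
    utils
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
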