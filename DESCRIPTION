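Package: acuitysim
Title: Simulated Visual Acuity Staircases and Method-Agreement Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Explicit, testable implementations of two smartphone visual
    acuity protocols: a distance-based staircase in which a fixed-size
    optotype is moved between 15 and 300 cm along a logarithmic (0.1 logMAR)
    grid, and a letter-size threshold protocol descending from 0.7 logMAR
    with a three-of-five pass criterion. Includes the viewing-distance to
    logMAR geometry, a psychometric-function observer model with Bangerter
    filter blur for simulating amblyopic cohorts, an end-to-end repeated
    measures study pipeline, and Bland-Altman agreement statistics (bias,
    limits of agreement, paired t-tests, line-difference distributions,
    interocular acuity differences).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
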