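Package: hrtrack
Title: Simulation and Evaluation of High-Residence Acoustic Telemetry
    Positioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fine-scale acoustic telemetry positioning with
    high-residence (HR) tags: a detection simulator for receiver arrays
    (jittered transmission schedules, sound propagation, range-dependent
    detection loss, stationary and moving tag trajectories), an exact
    two-dimensional time-difference-of-arrival (TDOA) positioning engine
    that solves every three-receiver subset and combines subsets by an
    error-sensitivity-weighted mean, accuracy and precision summaries for
    stationary and moving trials, and a track-thinning sensitivity
    analysis relating movement metrics (distance travelled, speed,
    turning angle) to tag transmission period.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    geosphere,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
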