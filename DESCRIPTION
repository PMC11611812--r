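Package: ipastpupil
Title: Pupil Dynamics and Task Modulation in the Interleaved Pro-/Anti-Saccade Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for analysing pupil dynamics recorded during
    the interleaved pro-/anti-saccade task (IPAST). Converts raw eye-tracker
    pupil area to millimetres via false-pupil calibration, cleans 500 Hz traces
    (despiking, blink handling, boxcar smoothing), detects saccades and
    classifies trials by saccadic reaction time, extracts eight pupil measures
    per trial, tests task modulation (ANTI minus PRO) with Wilcoxon signed-rank
    tests, runs exploratory factor analysis (principal axis factoring with
    direct oblimin rotation, KMO and Bartlett adequacy checks) on pupil and
    saccade measure tables, correlates pupil with saccade factors under
    Bonferroni correction, and fits lifespan age trajectories with
    penalized-spline generalized additive models whose first-derivative
    simultaneous confidence bands delimit significant periods of change.
    A seeded synthetic-cohort generator emulates the task timeline and known
    age trends so every stage is testable without raw recordings.
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
    mgcv,
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
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
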