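Package: tdgv
Title: Detecting Cognitive Distraction from Dashboard Glance Regularity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Streaming detector of cognitive distraction in drivers based on
    the temporal variance of dashboard glances (TDGV). Gaze samples labeled
    with areas of interest are reduced to inter-glance gap durations held in
    a fixed-size window; the rolling standard deviation of that window is
    smoothed, differentiated, and accumulated while rising, and a threshold
    calibrated from an undistracted baseline segment flags distraction.
    Includes segment-level evaluation (accuracy, sensitivity, specificity),
    baseline-quality diagnostics, self-report distraction scoring, and a
    seeded renewal-process simulator of AOI-labeled gaze streams for testing
    the whole pipeline without eye-tracker hardware.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
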