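Package: actiprofile
Title: Analytical and Translational Metrics for 24-Hour Accelerometer Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for summarising wrist-, hip- or thigh-worn raw
    accelerometer data into interpretable 24-hour physical activity
    profiles.  Computes per-sample ENMO (Euclidean norm minus one g),
    aggregates it into fixed epochs, screens days and participants for
    wear validity, and imputes non-wear by time-of-day averages.  From
    the cleaned series it derives the analytical metrics average
    acceleration (volume) and intensity gradient (log-log slope of the
    intensity distribution), and the translational MX metrics (the
    acceleration above which the most active X minutes of the day are
    accumulated).  Post-hoc translation utilities compare MX values with
    cut-point registries, cohort percentiles, within-metric z-scores and
    tertile profiles, and radar plots visualise raw, standardised and
    percentile-shaded activity profiles.  A synthetic-cohort generator
    with known volume and intensity-distribution slope provides a fully
    controlled test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
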