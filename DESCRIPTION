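Package: gdcr
Title: Adaptive Control of Gait Detection and Classification Rate from
    Ankle-Worn Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Threshold-based gait detection and classification for raw
    30 Hz inertial measurement unit (IMU) logs recorded at the ankle, and
    an adaptive controller that steers the gait detection and
    classification rate (GDCR) toward a target by adjusting an
    acceleration threshold.  Gaits are detected from medial-lateral
    angular velocity crossing a gyroscopic threshold (GT) and classified
    from the mean sagittal acceleration magnitude against an acceleration
    threshold (AT).  The package calibrates a logistic model of the
    population GDCR-versus-AT curve, inverts it in closed form to choose
    thresholds, simulates virtual subjects and walking-speed scenarios to
    benchmark control strategies, and provides nonparametric rank
    statistics for the resulting traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lhs
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
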