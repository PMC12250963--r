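Package: limbkin
Title: Dual-IMU Joint Kinematics and Gait Analysis for Lower-Limb Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for a two-unit wearable inertial sensor worn
    across a lower-limb joint (knee or ankle): gyroscope-bias and six-position
    accelerometer calibration, Madgwick gradient-descent orientation fusion,
    sagittal joint-angle computation by pitch summation, flexion-extension
    cycle segmentation with range-of-motion summaries, gait event detection
    (step peaks, step times, toe-off), and the agreement statistics used to
    compare a device against a gold standard (correlation line, Bland-Altman
    limits of agreement, percentage error, normality-gated two-sample tests).
    Includes a ground-truth simulator of two-segment hinge motion so the whole
    pipeline is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
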