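Package: sprintfusion
Title: Sprint Velocity Estimation by GNSS-IMU Sensor Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates instantaneous running velocity and sprint duration
    from a single trunk-worn GNSS-IMU unit.  A gradient-descent quaternion
    orientation filter expresses the accelerometer signal in a sprint-aligned
    global frame; two cascaded one-dimensional Kalman filters then segment
    the sprint precisely and fuse the inertial acceleration with the GNSS
    ground speed.  Includes first- and second-order exponential
    velocity-profile models with force-velocity and power-velocity
    profiling, agreement statistics (Bland-Altman limits of agreement,
    Lin's concordance correlation), and a synthetic sprint-session
    simulator for end-to-end verification against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
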