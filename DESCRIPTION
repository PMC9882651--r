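Package: headstats
Title: Natural Head-Orientation Statistics and Empirical-Prior Models of Tilt Perception
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for six-degree-of-freedom head odometry recorded
    during unconstrained natural behavior. Provides calibration of the sensor
    frame to an anatomically defined head frame from nod/shake/static
    calibration movements, confidence- and velocity-based exclusion rules with
    low/high linear-velocity partitioning, distributional summaries and kernel
    density estimates of head pitch and roll, decomposition of head-frame
    linear acceleration into gravitational and inertial components with
    Welch power spectra and gravitational-to-inertial crossing points, and a
    one-parameter Bayesian model of tilt-perception bias in which the measured
    orientation distribution serves as the prior. A synthetic odometry
    generator with matched marginal, spectral, and artifact structure makes
    every stage testable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
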