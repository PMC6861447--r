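Package: reachkin
Title: Wrist-IMU Reach Kinematics and Concurrent Validation Against Optical Motion Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes wrist-worn inertial sensor recordings of upper-limb
    reach-and-manipulate tasks (block transfer, drinking, pouring) into clinical
    kinematic metrics: total movement time, peak velocity, and spectral arc
    length. The inertial chain combines a Madgwick attitude filter, earth-frame
    gravity removal, Butterworth-envelope stationary detection, and
    zero-velocity-update (ZUPT) drift-corrected dead reckoning. A parallel
    reference chain processes optical marker trajectories (predicted-MSE
    smoothing spline, central-difference velocity). Concurrent validity between
    the two systems is quantified with Pearson correlation, ICC(2,1) with
    F-based confidence intervals, and Bland-Altman agreement statistics. A
    seeded minimum-jerk trial simulator generates paired sensor/marker
    recordings with exact ground truth so the full chain is testable without
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
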