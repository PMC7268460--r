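Package: selfpace
Title: Self-Paced Treadmill Control from Force-Plate Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and control for self-paced force-instrumented
    treadmills. Implements a per-footstep-corrected Kalman filter that
    tracks a walker's fore-aft speed and position from two-belt force-plate
    signals (vertical and fore-aft ground reaction forces and center of
    pressure), a once-per-footstep belt-speed control law, a physically
    consistent virtual walker and treadmill simulator for exercising the
    full estimate-control loop without hardware, and walking-speed
    evaluation metrics (per-step RMS errors, convergence time and distance,
    section speeds, linear fits, intra-subject variability).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
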