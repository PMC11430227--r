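Package: hybridarm
Title: Movement-Based Prosthesis Control Simulation with Angular
    Trajectory Interpolation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale simulator of movement-based trans-humeral
    prosthesis control. A seven degree-of-freedom kinematic arm model maps
    anatomical joint angles to hand pose in a shoulder-centred frame;
    feed-forward neural networks predict 'goal' distal joint
    configurations from target context (position and grasp-axis
    orientation) and, optionally, the proximal shoulder angles; an angular
    interpolation controller drives the five distal joints smoothly toward
    the saturated goal at a rate set by the user's locked-hand speed and
    the remaining distance to the target. Includes a synthetic
    natural-movement generator (minimum-jerk pick-and-place trajectories
    within joint ranges of motion), closed-loop trial simulation with
    target validation zones, offline trajectory reconstruction, and the
    associated online and offline trajectory metrics (success rate,
    movement and validation times, spectral arc length, trajectory
    curvature, distance index, shoulder spread volume, and reconstruction
    error distances).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
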