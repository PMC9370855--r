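Package: gaitcast
Title: Short-Horizon Pedestrian Trajectory Prediction from Gait Biomechanics
Version: 0.1.0
Authors@R:
    person("gaitcast", "developers", email = "gaitcast@example.org",
           role = c("aut", "cre"))
Description: Tools for real-time short-term (about one second) prediction of a
    walking person's position from a waist-level landmark tracked at a fixed
    sampling rate. Implements the four discrete kinematic motion models
    (constant velocity, constant acceleration, constant turn rate and
    velocity, constant turn rate and acceleration), state estimation from
    sampled positions with a Butterworth acquisition prefilter, an offline
    polynomial-regression baseline, and a causal gait-biomechanics
    compensation that holds the forward speed between foot-contact events and
    blends the position-derived heading with pelvis yaw to cancel the
    counter-phase step oscillation. Includes a recursive horizon-error
    evaluation protocol and a synthetic gait simulator with ground truth for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
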