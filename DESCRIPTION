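Package: pursuitpm
Title: Smooth-Pursuit Gain and Prediction-Motion Timing Analysis for
    Rolling-Wheel Tracking Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing prediction-motion (occluded tracking)
    experiments in which observers pursue a target rolling like a wheel
    across the screen inside global-local compound backgrounds. Provides
    the full chain from experiment design enumeration and cycloidal
    stimulus kinematics, through a synthetic gaze-and-response observer,
    central-difference velocity derivation, acceleration-threshold
    saccade detection and desaccading, interval-wise smooth-pursuit
    velocity gain, constant and variable timing error with 3-SD trimming,
    to within-subject ANOVA with partial eta squared and
    Bonferroni-corrected pairwise comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
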