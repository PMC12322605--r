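Package: handrot
Title: Hand-Rotation Kinematics and Age-Group Analysis from Hand Landmark Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying hand motion control from webcam-derived 21-landmark
    hand trajectories. Computes the palm rotation-angle signal from the wrist to
    thumb-tip vector, segments it into full pronation/supination rotations via
    5-frame slope sign reversals, derives seven per-trial kinematic indicators
    (rotation count, cumulative time and angle, and signed between-rotation change
    measures), screens participants against Purdue Pegboard norms, and fits a
    marginal (GEE-type) mixed-design model with exchangeable working correlation,
    robust standard errors, Bonferroni-adjusted post-hoc trial comparisons and
    Hedges g effect sizes. A synthetic-data module generates landmark trajectories
    and full cohorts with programmed ground truth so the whole pipeline is testable
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
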