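Package: armkin
Title: Kinematic Assessment, Motor Learning and Test-Retest Reliability for
    Gravity-Supported Upper-Limb Reaching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing upper-limb reaching assessments performed in
    a planar gravity-support exoskeleton 'catch' exercise. Parses raw 64 Hz
    trajectory logs with target event streams, segments trials into unitary
    movements between consecutively caught targets, and computes task time,
    movement time, peak velocity, hand path ratio, number of velocity peaks,
    game score and the timing of the velocity peak. Provides the downstream
    assessment statistics: Tukey-fence outlier screening, two-way
    repeated-measures ANOVA with Mauchly sphericity diagnostics,
    Greenhouse-Geisser correction and Tukey HSD post-hocs for learning and
    retention analysis, and test-retest reliability via ICC(2,k) with
    F-based confidence bounds, standard error of measurement and minimal
    detectable change. A calibrated synthetic-cohort generator built on
    minimum-jerk submovement trajectories supplies ground-truthed data for
    validation and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
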