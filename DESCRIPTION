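Package: reachprime
Title: Workspace-Redundancy Priming and Single-Trial Visuomotor Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a two-session center-out reaching
    paradigm in which target shape (arc versus radial line) makes one spatial
    dimension of movement -- direction or extent -- task-redundant during a
    priming phase, and single-trial adaptation to rotation and gain
    perturbations of endpoint feedback is probed in a subsequent test phase.
    Provides a constrained pseudorandom trial scheduler, a generative agent
    with planning and execution noise and dimension-specific aim correction,
    trajectory kinematics (movement offset detection, Savitzky-Golay velocity,
    path curvature), trial-exclusion rules, IQR-based explored-variability
    statistics, per-subject multilinear regressions of single-trial motor
    corrections, and group-level inference (within-subject ANOVA, Bonferroni
    corrected t tests, Fisher-z correlation tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
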