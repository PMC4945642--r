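Package: hrfboost
Title: Informed Basis Set and Derivative-Boost Analysis for fMRI Group Studies
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to study the consequences of modeling latency-shifted BOLD
    responses with the informed basis set (canonical double-gamma hemodynamic
    response function plus its first temporal derivative). Provides first-level
    ordinary least-squares GLM estimation, derivative-boost amplitude
    estimation constrained by voxelwise time-to-peak, second-level
    summary-statistics random-effects inference, intrinsic spatial smoothness
    estimation, and random-field-theory cluster-extent thresholding, together
    with synthetic single-voxel and multi-subject BOLD generators that supply
    ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
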