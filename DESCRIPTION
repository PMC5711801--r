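Package: bimphase
Title: Relative-Phase Analysis and Bayesian Factorial Modelling of Bimanual Finger Oscillations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing rhythmic bimanual coordination experiments of
    the finger-oscillation type. Converts raw two-hand lateral finger
    trajectories into per-cycle relative-phase estimates (missing-sample
    interpolation, zero-phase Butterworth smoothing, extremum-based cycle
    segmentation, per-cycle sine fitting), dichotomizes cycles into
    correct/incorrect against the instructed movement pattern, and fits a
    hierarchical Bayesian logistic regression over the full factorial design
    (movement instruction, mirror view, hand posture, movement speed) with
    sum-to-zero effect coding, an in-package adaptive MCMC sampler,
    highest-density-interval inference, and a posterior-predictive credible-
    difference contrast suite. Includes a synthetic-data generator that
    emulates the structure of mirror-feedback finger-oscillation experiments
    for testing and power analysis, plus delimited-text file formats and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    coda,
    optparse,
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
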