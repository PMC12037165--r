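Package: graspcode
Title: Encoding and Decoding of Grip Type and Pulling Force in Motor
    Cortex Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for time-varying encoding of grip type and
    pulling force in simultaneously recorded motor-cortex populations
    during a delayed reach-to-grasp task. Provides a task-structured
    inhomogeneous-Poisson spike simulator, causal-exponential and binned
    firing-rate estimation aligned to movement onset, time-resolved auROC
    selectivity with permutation significance and selectivity classes, a
    grip-force independence battery (permuted chi-square marginal test,
    covariance-ellipse angle, shuffled-null delta-auROC correlations),
    demixed principal component analysis with single-trial component
    classifiers, cross-temporal linear decoding with a three-condition
    static-bin criterion and a generalization index, behavioral and
    force-signal statistics, and figure/manifest reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
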