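Package: holocyto
Title: Label-Free Lensless Microflow Cytometry Classification with
    Measurement-Bias Control
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for label-free particle classification from raw inline
    holographic interference patterns in microflow cytometry, together with
    the machine-learning bias-control methodology the approach requires: a
    synthetic lensless holo-cytometer frame simulator (angular-spectrum
    scalar propagation, Poisson particle arrivals, per-session illumination
    drift), background-subtraction preprocessing with a perturbation-based
    frame acceptance rule, acceptance-threshold calibration against a target
    particle ratio, Mann-Whitney per-pixel class-separation feature
    selection, an L2-regularised logistic readout, session-intertwined
    nested cross-validation with a uniform-mislabelling bias test, and an
    analytic Poisson field-of-view sensitivity model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
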