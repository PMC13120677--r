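Package: flukeprint
Title: Whale Size Class, Speed and Orientation from Drone Thermal Flukeprints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for inferring humpback whale size class, swimming speed and
    orientation from flukeprints (tailbeat surface disturbances) annotated in
    synchronized drone thermal-infrared and RGB imagery. Provides nadir
    photogrammetric scaling from pixels to metres, per-individual morphometric
    summaries with logistic/ROC age-class discrimination, a method-agreement
    battery (Bland-Altman, ICC(A,1), Deming regression) comparing
    flukeprint-spacing speeds against RGB track speeds, a log-log
    random-intercept mixed model predicting speed from flukeprint spacing with
    propagated 95% prediction intervals and leave-one-whale-out validation,
    circular statistics for heading agreement, and a synthetic dual-sensor
    survey generator with known ground truth so every stage is testable
    without field footage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
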