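Package: grfimu
Title: Ground Reaction Force Estimation from Body-Worn Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates ground reaction forces and moments, joint angles and
    joint torques during dynamic whole-body movements from inertial
    measurement units (IMUs) alone, without force plates.  A 12-segment,
    27-degree-of-freedom rigid-body human model is driven by
    proportional-derivative joint torques toward spline-parameterized
    reference joint angles; a viscoelastic 22-point-per-foot contact model
    supplies ground reaction forces; segment orientations are fused from
    paired accelerometer/gyroscope signals with an extended Kalman filter
    that is insensitive to dynamic acceleration; and the reference-angle
    spline nodes are optimized with a genetic algorithm against the fused
    orientation and pelvis-acceleration measurements plus a normalized
    muscle-load penalty.  Includes a synthetic-trial generator, validation
    metrics (Pearson correlation with qualitative bands, RMSE, relative
    RMSE on phase-normalized, body-size-normalized curves), and CSV/YAML
    interfaces for trials and run configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    graphics,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
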