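Package: cwsifusion
Title: Crop Water Stress Diagnostics from Thermal and RGB Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Field-oriented diagnosis of crop water stress from paired
    thermal and RGB imagery together with plant growth indicators. Implements
    a field-observable crop water stress index (CWSI) built from a soil
    moisture and humidity driven correction coefficient, thermal and RGB
    frame calibration and preprocessing (color-checker correction, gamma,
    histogram equalization, vegetation segmentation, quality control),
    random-forest feature ranking with growth-stage tabular classifiers, a
    dual-branch CNN plus transformer fusion classifier over RGB-thermal
    pairs with thermal channel masking and Grad-CAM explanations, and a
    probability-averaging decision layer that emits irrigation
    recommendations. A seeded synthetic data generator emulates the full
    acquisition stack so every component is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    EBImage,
    randomForest,
    e1071,
    nnet,
    caret,
    pracma,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
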