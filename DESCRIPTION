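Package: ovisense
Title: Behaviour and Lameness Classification from Tri-Axial Accelerometers on Sheep
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An epoch-based pipeline for classifying sheep behaviour, including
    lame gait, from tri-axial accelerometer signals recorded by ear-, collar-
    or leg-mounted sensors. Raw acceleration records are segmented into
    mutually exclusive 10 second behaviour epochs, fourteen movement metrics
    (per-axis means and extrema, movement variation, signal magnitude area,
    average intensity, entropy, energy) are extracted per epoch, features are
    ranked by random-forest mean decrease in Gini impurity, and the top-ranked
    subset drives a quadratic discriminant classifier validated by
    leave-one-out cross-validation with confusion-matrix performance
    statistics. A seeded synthetic gait-signal generator emulates standing,
    lying, grazing, walking and lame-gait regimes so the full pipeline is
    testable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    randomForest,
    withr
Config/testthat/edition: 3
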