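Package: fundoscreen
Title: Glaucoma Screening from Color Fundus Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end glaucoma screening engine for color fundus
    photographs: morphological optic-disc localization by sliding-window
    confidence over intensity and vessel feature maps, simultaneous
    optic-disc/optic-cup segmentation with an encoder-decoder network that
    adds a concatenating path and a fusion (cross-entropy + Dice) loss,
    ellipse-based post-processing, extraction of 25 cup-to-disc-ratio and
    ISNT-rule clinical features, and an imbalance-aware classifier (SMOTE
    oversampling plus gradient-boosted decision trees) with 10-fold
    cross-validated evaluation. Ships a seeded synthetic fundus-image
    generator with ground-truth masks so the whole pipeline is testable
    without any dataset download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    randomForest,
    Rcpp,
    stats,
    utils,
    xgboost
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
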