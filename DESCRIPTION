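Package: subtracad
Title: Temporal-Subtraction Mammography CAD with Synthetic Sequential Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computer-aided detection and classification of breast masses from
    temporally sequential mammograms. The prior screening view is contrast
    enhanced (CLAHE, gamma correction, border removal), registered onto the
    recent view with a Demons deformable registration (affine baseline
    included), and subtracted; candidate masses are segmented from the
    residual by thresholding, morphological cleaning and peripheral removal,
    described by a fixed 98-value feature vector (gray-level co-occurrence
    matrix texture, first-order statistics, intensity and shape), reduced by
    majority-rule consensus over eight feature-ranking methods, and
    classified in two rounds (normal tissue vs. mass, then benign vs.
    malignant) with SMOTE-balanced classifiers under patient-wise
    cross-validation. A seeded synthetic sequential-mammogram generator with
    ground-truth deformations, masses and density classes makes every stage
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    MASS,
    e1071,
    randomForest,
    rpart,
    xgboost,
    nnet,
    stats,
    utils,
    grDevices,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
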