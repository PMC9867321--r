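Package: pattyHSI
Title: Near-Infrared Hyperspectral Classification of Processed Beef Patties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for authenticating raw beef patties with near-infrared
    hyperspectral imaging (NIR-HSI). Implements the full object-wise analysis
    chain: radiometric calibration of raw irradiance cubes against dark and
    grey reference frames, pseudo-absorbance conversion, threshold-based
    segmentation and mask cleaning, mean-spectrum extraction, chemometric
    pre-processing (mean-centring, standard normal variate, detrending),
    principal component analysis with influence-based outlier screening, a
    suite of discriminant classifiers (LDA on scores, KNN on scores, decision
    trees, random forests, four SVM kernels, NIPALS PLS-DA), leave-one-out
    cross-validation, grid search, and one-vs-rest performance measures with
    a regulatory acceptance flag. Because no public hyperspectral patty data
    set exists, the package includes a physically motivated synthetic capture
    generator that emulates the four South African patty categories from
    their published proximate compositions and absorption band assignments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    e1071,
    rpart,
    randomForest,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
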