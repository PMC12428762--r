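Package: shellcolor
Title: Batch Correction, Classification and Colour-Index Construction for
    Blue-Green Eggshells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing CIELab colour measurements of blue-green
    chicken eggshells against ordinal visual colour scores assigned by a
    panel of observers.  Provides empirical-Bayes (ComBat-style) batch
    correction of L*, a*, b* readings with the visual score preserved as a
    covariate, multi-class linear discriminant analysis with extractable
    discriminant functions, comparator classifiers (random forest, radial
    SVM, single-layer neural network) with confusion-matrix metrics and
    noise-sensitivity evaluation, construction and grid-scan optimisation
    of simplified shell-colour indices of the form L*-kb* and L*-kC*,
    Fisher-Z comparison of index correlations, threshold-based grading of
    eggs into light/blue/green/olive classes, and a calibrated synthetic
    data generator so the full pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    e1071,
    jsonlite,
    nnet,
    randomForest,
    stats,
    utils
Suggests:
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
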