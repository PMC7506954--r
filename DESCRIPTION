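Package: carrygait
Title: Load Position and Weight Classification During Carrying Gait from
    Wearable Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for classifying how a load is carried
    during walking from wearable-sensor recordings: full-body joint angles
    (22 joints in 3 planes at 240 Hz) and bilateral erector spinae surface
    electromyography (2148 Hz). Trials are segmented into left and right
    steps from heel-strike events; per-step moments of the joint-angle
    signals and of the MVC-normalized EMG envelope yield a 538-dimensional
    trial feature vector. Sequential floating forward selection with an
    adaptive partial-F p-value threshold reduces the feature set, and four
    classifiers (regression-rounded least squares, linear discriminant
    analysis, linear-kernel support vector machine, and a bagged tree
    ensemble) are evaluated by leave-participant-out cross-validation over
    five load-position and load-asymmetry classification problems. A seeded
    synthetic cohort generator reproduces the statistical structure the
    analysis relies on, so the whole pipeline is testable end to end
    without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    randomForest,
    signal,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
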