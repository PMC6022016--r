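Package: fallvar
Title: Human Fall Detection from Video via Temporal-Variance Features and
    Boosted Gain-Ratio Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects human falls in surveillance video on a per-frame basis.
    A moving person is segmented from each frame by background subtraction,
    distance-transform noise suppression, morphology and connected-component
    filtering; six motion and geometry descriptors (bounding-box aspect ratio,
    fitted-ellipse person angle and axis ratio, upper-half bounding-box area,
    boundary geometric centre, centroid motion magnitude) are reduced to their
    temporal variances over a sliding 30-frame window; frames are then labelled
    fall / sitting / no-fall by an AdaBoost ensemble of gain-ratio (C4.5-style)
    decision trees. Includes a synthetic fall-video simulator with ground-truth
    labels so the whole pipeline is testable without external datasets, plus
    stratified cross-validation, sensitivity/specificity and ROC evaluation
    utilities and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    zoo,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
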