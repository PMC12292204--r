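Package: eegsep
Title: Interpretable Separable Convolutional Networks for Task EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trial-level classification of multichannel task EEG with a
    seven-layer interpretable convolutional network built from a pointwise
    spatial-demixing stage and a depthwise temporal stage, trained with Adam
    under early stopping and evaluated with a seeded
    leave-p%-subjects-out cross-validation protocol.  Includes a synthetic
    cohort generator that plants band-limited oscillations and artifacts on
    a 1/f background over a standard 10-10 montage, self-contained ROC AUC,
    Cohen's kappa and sensitivity metrics, and class-activation-style
    relevance maps with band-power topographies and localization scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
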