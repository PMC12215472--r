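Package: fuzzyfuse
Title: Fuzzy-Logic Dynamic Weighting for Multi-Classifier Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Combines class-probability outputs from several image
    classifiers with per-sample dynamic weights derived from model
    confidence scores through a Mamdani fuzzy inference system, alongside
    fixed-weight averaging, mean-voting and majority-voting baselines.
    Includes multi-class evaluation metrics (accuracy, precision, recall,
    F1, average confidence score), a run-based statistical validation
    protocol (mean, standard deviation, 95% confidence intervals, one-way
    ANOVA), a challenge-set generator with seeded augmentation,
    salt-and-pepper noise injection and synthetic occluders, and a
    calibrated simulator of multi-model classifier predictions for
    end-to-end testing without trained networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
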