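Package: saliencybench
Title: Bias-Aware Benchmarking of Visual Saliency Models Against
    Fixations and Explicit Judgments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating visual-saliency models against
    eye-tracking fixations and explicit "most salient location"
    judgments. Implements standard and shuffled ROC/AUC scoring with
    exact midrank tie handling, Gaussian fixation-density maps,
    per-image and dataset-level inter-observer congruency, quantification
    of the spatial (center) bias of algorithm output and its removal by
    per-pixel rank ordering or whitening, precision-recall/F-measure
    scoring against object masks, a bagged-regression-tree predictor of
    explicit-judgment locations from saliency and fixation features, a
    sampler that converts predicted judgment maps into surrogate
    point data, and a seed-deterministic synthetic-data generator that
    emulates multi-observer, multi-task gaze datasets so the full
    pipeline is testable without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    randomForest,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
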