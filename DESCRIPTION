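Package: milwsi
Title: Weakly-Supervised Multiple-Instance Learning for Whole-Slide-Image
    Carcinoma Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for training and evaluating tile-based carcinoma
    classifiers on whole-slide images under two supervision regimes: a
    fully-supervised baseline driven by polygon region annotations, and a
    weakly-supervised multiple-instance-learning (MIL) loop that alternates
    sliding-window inference with training on the top-k highest-scoring
    tiles of each slide, using only slide-level diagnosis labels after a
    short annotation-driven warm phase. Includes slide tiling and tissue
    masking, GeoJSON region-annotation handling with a carcinoma-priority
    slide label rule, max-probability slide aggregation, tumor-probability
    heatmaps, ROC AUC / log-loss evaluation with percentile bootstrap
    confidence intervals, and a synthetic-cohort generator that emulates
    the necrosis/inflammation tile-label noise that motivates weak
    supervision.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
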