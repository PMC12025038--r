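Package: fssmr
Title: Firefly Sigma Seeker Early Stopping and MagWeight Rank Pruning for
    Multi-Stream Kidney Lesion Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Joint lesion segmentation and four-class kidney-condition
    classification (normal, cyst, stone, tumor) with small convolutional
    networks trained under two coupled optimization techniques: Firefly
    Sigma Seeker (FSS), an adaptive early-stopping rule whose threshold is
    proportional to the dispersion of recent validation losses and whose
    sensitivity parameters are tuned by a firefly-swarm search, and
    MagWeight Rank (MWR), magnitude-threshold weight pruning driven by each
    layer's mean absolute weight. Includes single-stream and multi-stream
    (plain plus dilated pathway) architectures with segmentation and
    classification heads, a synthetic CT-phantom generator with paired
    lesion masks for desk-scale experiments, SGD-with-momentum training
    with a step learning-rate decay, evaluation metrics, and command-line
    entry points for simulation, training, pruning, tuning and dataset
    inventory.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    Rcpp,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
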