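Package: pestlite
Title: Lightweight YOLOX-Style Detection Toolkit for Larval Pest Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds, trains, compresses and evaluates lightweight one-stage
    anchor-free detectors for larval pests of swallowtail butterflies
    (classes "young" and "old") in orchard imagery. Provides the Ghost
    module and Ghost-ECA bottleneck backbone blocks, the tanh-softplus (TS)
    activation, efficient channel attention, adaptive spatial feature fusion
    across pyramid levels, soft non-maximum suppression driven by
    distance-IoU, batch-norm scaling-factor (gamma) channel pruning with L1
    sparsity training and fine-tuning, a two-phase transfer-learning
    schedule with cosine annealing, PASCAL VOC annotation I/O with
    photometric and geometric augmentation, detection metrics (precision,
    recall, F1, average precision, mAP, FPS), and a seeded synthetic orchard
    scene generator so the whole pipeline is exercisable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    jpeg,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
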