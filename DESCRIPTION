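Package: cbryolo
Title: Lightweight Anchor-Free Detection of Beef-Cattle Behaviour
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds, trains and evaluates CBR-YOLO, a lightweight
    single-stage anchor-free detector for beef-cattle behaviour recognition
    (standing, walking, eating, lying). Provides the StarNet star-operation
    backbone, an SPPF layer augmented with large separable kernel attention,
    a multi-convolutional focused pyramid neck with ADown down-sampling, a
    group-normalised weight-shared detection head, and the Inner-MPDIoU
    bounding-box regression loss, together with a YOLOv8n reference baseline
    for structural comparison. Includes YOLO-format dataset input/output,
    standard photometric and geometric augmentation, atmospheric weather
    synthesis by transmittance blending, precision/recall/mAP evaluation,
    exact per-module parameter and FLOP accounting, and a synthetic-scene
    generator so the whole stack runs on CPU without the original dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
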