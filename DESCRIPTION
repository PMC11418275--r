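Package: jujubedet
Title: Lightweight Hybrid Convolution-Transformer Detection and RGB-D
    Localization of Winter Jujube
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and profiles lightweight anchor-free fruit detectors in
    pure R: a YOLOv8n baseline and a reduced variant that reconstructs the
    backbone with MobileViT hybrid convolution-transformer stages, adds a
    large-selective-kernel (LSK) spatial attention module at the P3 neck
    scale and replaces dense neck downsampling convolutions with GSConv.
    Includes exact trainable-parameter and FLOP accounting, a synthetic
    orchard-scene generator with YOLO-format annotations, dataset split and
    augmentation arithmetic, a desk-scale SGD training loop, detection
    decoding with non-maximum suppression, precision/recall/average-precision
    metrics, and pinhole deprojection plus quaternion hand-eye geometry that
    maps detected fruit centres and depth readings into robot-base
    coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
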