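Package: wildedge
Title: Drone-Based Wildlife Detection Support: Tiling, Evaluation and
    Edge Notification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools supporting small-object wildlife detection from
    high-resolution drone imagery in low-connectivity settings: overlapping
    image tiling with area-based label retention, YOLO-format annotation
    reading/writing and QC overlays, leakage-free train/validation splits by
    source video, label-aware augmentations (mosaic, mixup, flips), detector
    evaluation (IoU, precision-recall, per-class AP, mAP, confusion matrix
    with a background class), a configurable noisy-oracle detector, a
    lightweight at-least-once publish/subscribe notification layer with
    throttling and a GeoJSON sink, and a seeded synthetic aerial-scene and
    flight generator so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
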