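Package: headcount
Title: Detection and Counting of Sorghum Heads in UAV Field Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-step machine-learning pipeline for detecting and counting
    sorghum heads (panicles) in high-resolution RGB images taken by unmanned
    aerial vehicles over breeding trials. Pixels are classified into seven
    scene classes with a decision-tree segmentation model over nine color
    features (r, g, b; H, S, V; CIE L*, a*, b*); connected head regions are
    characterized by eleven morphological features and assigned a head count
    by a quadratic-kernel support vector machine. Includes point-annotation
    detection evaluation (precision, recall, F-measure, counting R-squared),
    georeferenced plot extraction, and a synthetic sorghum-field image
    generator with full ground truth for training and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    e1071,
    grDevices,
    jpeg,
    jsonlite,
    png,
    rpart,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
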