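Package: segmetrics
Title: Per-Object Evaluation of Instance Segmentation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Supervised evaluation of multi-object instance segmentation
    against a hand-segmented ground truth. Compares a test label image with a
    ground-truth image encoded under the four-color convention, computing both
    traditional pixel-level Precision/Recall/F-measure and per-object metrics:
    each ground-truth object is matched to the test object with the largest
    pixel overlap (modal matching) and true-positive, false-positive and
    false-negative pixels are tallied per object and per image. Includes
    grayscale TIFF/PNG label-image I/O, per-object CSV reports, a synthetic
    fixture generator for validation images (constant fields, half images,
    adjacent-object pairs, randomized cell fields with known per-object truth),
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    generics,
    ggplot2,
    igraph,
    png,
    tibble,
    tiff,
    utils
Suggests:
    EBImage,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
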