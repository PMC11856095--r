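Package: lungprep
Title: Lung CT Slice Preprocessing, Mask Filtering and Quality Control
Version: 0.1.0
Authors@R:
    person("lungprep", "developers", email = "lungprep@example.org",
           role = c("aut", "cre"))
Description: Classical preprocessing for lung segmentation from 2-D CT
    slices: min-max normalization, percentile contrast stretching, Otsu
    binarization, binary morphology (5x5 structuring element, iterated
    closing), body isolation and lung-candidate extraction, rule-based
    mask acceptance filters (border contact, object count, area and
    aspect-ratio checks), region-of-interest bounding boxes, and a
    quality-control battery for paired masks (IoU, Dice, precision,
    recall, specificity, percentage of lung coverage, left-right
    asymmetry, weighted quality score). Ships a seeded synthetic
    CT-phantom generator with exact ground-truth masks so every stage is
    testable without clinical data, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
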