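Package: anakit
Title: Segmentation and Texture Classification for Antinuclear Antibody
    Immunofluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A classical image-analysis pipeline for HEp-2 indirect
    immunofluorescence (IIF) slides used in antinuclear antibody (ANA)
    screening. Raw fields are cut into quadrants, reduced to the green
    fluorescence channel and min-max normalized; individual cells are
    segmented by Otsu thresholding followed by marker-based watershed with
    size, margin and brightness region filters; cell crops are described by
    LBP, co-occurrence LBP (CoALBP), rotation-invariant co-occurrence LBP
    (RIC-LBP) and pooled SIFT descriptors, optionally fused; and staining
    patterns are classified by a soft-voting ensemble of an RBF-kernel SVM,
    a distance-weighted k-nearest-neighbour classifier and a random forest.
    A synthetic fluorescence-scene generator with ground-truth masks makes
    the whole pipeline testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    e1071,
    randomForest,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
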