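Package: iimt
Title: Interval-Iteration Multilevel Thresholding for Grayscale Image
    Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multilevel thresholding segmentation of 8-bit grayscale images,
    aimed at brain MR slices. Implements exact multilevel Otsu threshold
    search, an interval-iteration refinement that re-runs single-threshold
    Otsu inside nested class-mean intervals until consecutive thresholds
    coincide, a hybrid L1-L0 base/detail layer decomposition solved by an
    augmented-Lagrangian (ADMM) scheme, similarity-weighted fusion of two
    candidate label maps, and four segmentation quality measures (uniformity,
    misclassification error, Hausdorff distance, Jaccard index). A synthetic
    phantom generator with ground-truth labels makes the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
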