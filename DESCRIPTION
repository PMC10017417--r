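Package: podscan
Title: Silique Phenotyping from 3D Point Clouds by Skeletonization and
    Hierarchical Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Separates siliques (seed pods) from whole-plant 3D point clouds
    of oilseed rape (Brassica napus) and quantifies silique number, length and
    volume. The pipeline removes outlier noise and the pot by slab-wise
    least-squares circle fitting, contracts the cloud to an L1-median skeleton
    under a RANSAC-plane neighborhood constraint, clusters skeleton points
    with DBSCAN, connects each cluster into an ordered polyline with a
    direction-corrected weighted graph search, repairs over- and
    under-segmented sub-skeletons with angle and distance rules, and extracts
    per-silique morphological traits. A labeled synthetic plant generator and
    validation metrics make every stage testable without scanned data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
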