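Package: leafpheno
Title: Multi-Component Phenotyping of Detached Lettuce Leaves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated phenotyping of detached lettuce leaves from semantic
    component masks (blade, mid-rib, second-order veins, lamina, venation and
    marginal zone) and the matching RGB photograph. Provides mask set algebra
    for the derived components and area indicators, oriented-bounding-box
    leaf normalization into a fixed-width "size-free" space, skeleton- and
    lamina-based reconstruction of petiole and second-order vein architecture
    (attachment points and vein angles via Douglas-Peucker polygon
    simplification), a 266-trait vector per leaf (30 geometry, 20 venation,
    216 color traits over six color spaces), and cohort-level statistics
    (manual-agreement metrics, positive-back differences, decision-tree
    feature importance, PCA and hierarchical clustering). A seeded parametric
    synthetic-leaf generator with exact ground truth makes every stage
    testable without photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    png,
    jsonlite,
    igraph,
    rpart,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
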