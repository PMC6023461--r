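Package: spotscreen
Title: Image Analysis and Heteroscedastic Statistics for Cell-Array and
    Multi-Well RNAi Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a high-content screening analysis
    chain for comparing reverse-transfection cell arrays with multi-well
    plates: nuclei segmentation (rolling-ball background subtraction, global
    Otsu plus local mean thresholding, morphological cleanup, connected
    components), per-nucleus feature extraction, three-class mitotic
    phenotype scoring (normal / spindle / cytokinesis), perinuclear
    EGF-uptake quantification, spot-ROI handling and spot/well aggregation,
    and the heteroscedastic statistics layer (Welch one-way ANOVA,
    Games-Howell post-hoc with an internally implemented studentized-range
    distribution, replicate correlation, variance tests, and the
    replicate-equivalence calculation). A seeded synthetic image generator
    with full ground truth stands in for undeposited raw microscope images
    and makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    EBImage,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
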