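Package: lcnose
Title: Optical Electronic-Nose Signal Simulation, Feature Extraction and
    VOC Classification
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for single-channel optical electronic-nose
    recordings from liquid-crystal hybrid gel films: a synthetic-data
    generator emulating exposure/recovery assays, moving-window smoothing
    and cycle segmentation, twelve per-cycle features (nine morphological
    descriptors plus three logistic-fit parameters), a radial-basis-kernel
    support vector machine evaluated by stratified k-fold cross-validation
    with normalized confusion matrices, and film-optics utilities
    (tilt-corrected thickness, masked mean gray value, gray-value time
    series from image stacks).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
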