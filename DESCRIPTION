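Package: mammocad
Title: Breast-Mass Detection in Mammograms via Morphology, Template
    Matching, a Patch CNN and Particle-Swarm Box Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A four-stage computer-aided detection pipeline for breast
    masses in grayscale mammograms.  Suspected regions are highlighted by
    grayscale erosion and dilation with elliptical structuring elements,
    located by squared-difference matching against a synthesized circular
    mass template, classified into mass versus background by a small
    convolutional network trained on 200x200 patches, and their bounding
    boxes refined by particle swarm optimization using the network's mass
    probability as fitness.  Includes a seeded synthetic phantom generator
    with known ground truth, detection metrics (true-positive rate, false
    positives per image, precision/recall/F1), and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
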