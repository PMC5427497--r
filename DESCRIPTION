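Package: yeastloc
Title: Deep Convolutional Classification of Protein Subcellular
    Localization in Yeast Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies two-channel (cytosolic marker + GFP-tagged protein)
    64x64 single-cell fluorescence microscopy patches into twelve
    subcellular compartments.  Provides a from-scratch 11-layer
    convolutional network (eight 3x3 convolutional layers with batch
    normalization and three fully connected layers) trained by SGD with
    momentum, a classic hand-crafted feature baseline (intensity,
    geometry, Haralick, Gabor, Zernike families) with a random-forest
    classifier and cell-quality filter, Dirichlet-multinomial aggregation
    of per-cell class probabilities into per-protein compartment calls,
    stratified bootstrap confidence intervals for precision and recall,
    transfer learning from intermediate network activations to unseen
    compartment classes, and interpretability tools (t-SNE embeddings,
    neuron-class mutual information, feature correlations, maximally
    activating patches).  A parametric synthetic microscopy generator
    renders labelled two-channel cell images for all localization
    archetypes so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tiff,
    png,
    randomForest,
    EBImage,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    cluster,
    e1071,
    optparse
Config/testthat/edition: 3
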