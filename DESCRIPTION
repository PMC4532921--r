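Package: divRBM
Title: Diversity-Prior Regularized Restricted Boltzmann Machines for
    Early Visual Feature Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains binary restricted Boltzmann machines on natural-image
    patches with a diversity prior that penalizes pairwise squared cosine
    similarity between weight columns, mimicking lateral inhibition during
    learning. Provides the full preprocessing pipeline (pseudo-whitening,
    sigmoid rescaling, patch extraction, variance filtering), contrastive
    divergence training with exact small-instance likelihood and gradient
    oracles, Treves-Rolls selectivity and population-sparsity metrics,
    dead-neuron counting, reverse-correlation receptive-field estimation,
    Gabor fitting with quality control and shape-profile statistics, and
    deterministic patchwise image reconstruction. A synthetic image
    generator (1/f random fields with oriented edges and gratings) allows
    desk-scale experiments without external image databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    jsonlite,
    png,
    tiff
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
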