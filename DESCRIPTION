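Package: ipclversa
Title: Instance-Prototype Contrastive Learning and Voxel-Wise Encoding RSA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements instance-prototype contrastive learning (IPCL), a
    self-supervised objective in which several augmented views of an image are
    pulled toward their mean embedding (the instance prototype) on the unit
    hypersphere while being pushed away from a FIFO memory queue of recently
    encountered items, together with the readouts used to probe emergent
    category structure (similarity-weighted k-nearest-neighbour classification
    and linear probes).  Also provides the voxel-wise-encoding representational
    similarity analysis (veRSA) pipeline for scoring layerwise network features
    against multi-subject condition-by-voxel brain data: leave-one-condition-out
    ridge encoding models with efficient per-voxel lambda selection,
    model-predicted representational dissimilarity matrices, subject split-half
    layer curves, split-half noise ceilings, cross-validated max-layer
    estimation, and variance-corrected paired statistics over resampled splits.
    Procedural shape-world image generation and synthetic multi-subject voxel
    simulation make the full pipeline testable end to end at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
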