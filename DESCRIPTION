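Package: stamix
Title: Spatial Omics Clustering with a Gaussian Mixture Variational
    Autoencoder and Morphology Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Clustering of spatially resolved transcriptomics and
    proteomics data into spatial domains or cell types. Fits a Gaussian
    mixture variational autoencoder whose encoder is a single-hop graph
    attention network over a K-nearest-neighbour graph of units (spots
    or cells), and couples morphological image similarity directly to
    the predicted soft cluster labels through a dedicated loss term:
    units whose image patches embed closely are pushed to share soft
    labels. Includes a preprocessing chain for count matrices (unit and
    feature filtering, highly variable gene selection, library-size
    normalisation, log transform, z-scoring), affine alignment of
    coordinates to image pixel space, mini-batch neighbour sampling,
    integrated-gradients ranking of spatially variable genes per
    cluster, clustering evaluation metrics (adjusted Rand index,
    Fowlkes-Mallows index, silhouette), and a seeded generator of
    synthetic spatial omics fixtures with matched toy images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    mclust,
    cluster,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
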