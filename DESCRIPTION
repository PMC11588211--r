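Package: sducl
Title: Signal-Diffusion Unsupervised Contrastive Learning for Spatial
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns low-dimensional per-spot embeddings from spatial
    transcriptomics data by fusing gene expression, histology-derived image
    features and Katz spatial-topology features, then training a graph
    convolutional autoencoder jointly with a Deep-Graph-Infomax-style
    contrastive objective. The contrastive context for each spot is its
    "microenvironment": the subnetwork reached by heat-kernel signal
    diffusion exp(-alpha*L) on the spatial neighbour graph. Includes readers
    for 10x Visium, AnnData and CSV inputs, a synthetic spatial-domain data
    generator, clustering of the learned embeddings and the standard
    external (ARI, NMI, V-measure, Purity) and internal (Silhouette,
    Davies-Bouldin) evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    cluster,
    grDevices,
    graphics,
    jsonlite,
    mclust,
    png,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
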