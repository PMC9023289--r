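Package: spotdecon
Title: Topic-Model-Based Cell-Type Deconvolution and 3D Integration of
    Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decomposes the cell-type composition of spatial transcriptomics
    spots using topic models trained on annotated single-cell RNA-seq. Latent
    Dirichlet allocation (online variational Bayes) learns a gene-by-topic
    distribution shared between modalities; Bayes inversion of the topic-by-cell
    distribution yields a cell-type-by-topic table that converts per-spot topic
    distributions into cell-type proportions. Includes a ground-truth spot
    simulator (random mixtures, sequencing-depth series, and a structured
    tumor-microenvironment design with co-localized cell types), deconvolution
    performance metrics (per-spot and per-cell-type Pearson correlation,
    presence/absence-split RMSE), neighborhood-aware spatial domain clustering,
    topic-similarity mapping of single cells into spots, and serial-section 3D
    reconstruction via fused Gromov-Wasserstein optimal transport and weighted
    Procrustes alignment.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    grDevices,
    graphics,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
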