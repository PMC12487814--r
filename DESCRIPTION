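Package: chronocell
Title: Temporal Conditional Variational Autoencoders for Multicondition
    and Multimodal Single-Cell Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint modeling of single-cell time-series profiles across
    conditions and data modalities. A conditional variational autoencoder
    with a continuous sinusoidal time encoding decomposes each cell's
    profile into a time-invariant cell-identity embedding plus time,
    condition and batch factors, using a zero-inflated negative binomial
    likelihood for scRNA-seq counts and a Bernoulli likelihood for
    binarized scATAC-seq peaks. An adversarial time discriminator keeps
    cell embeddings time-invariant, and a shared temporal interaction
    layer couples modalities so that profiles can be imputed at
    unobserved time points, under swapped conditions (e.g. the opposite
    sex), or in a missing modality. Downstream statistics include
    rank-based sex-bias scoring over time, protein-protein-interaction
    odds-ratio permutation tests, and time-lagged cross-correlation
    between predicted gene-expression and chromatin-accessibility
    trajectories. A synthetic-data generator provides simulated
    time-series fixtures with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    pROC,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
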