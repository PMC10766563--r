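Package: CARDecon
Title: Cell-State Abundance Deconvolution Along Single-Cell Trajectories
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates the abundance of cells at fine-grained states along a
    one-dimensional trajectory (pseudotime) in bulk RNA-seq samples, using a
    single-cell reference. The focal cell state is fitted as a fixed effect in
    a linear mixed model while the remaining cells of the focal type are
    fitted individually as random effects with a conditional-autoregressive
    (CAR) covariance over trajectory distance; variance components are
    estimated once by REML under the null and plugged into generalized least
    squares for every state. Includes a Pillai-trace MANOVA on polynomial
    abundance profiles for group comparisons, a signature-gene-shuffling
    permutation test that corrects its inflation, cell-state-dependent eQTL
    interaction mapping with rank-based inverse normal transformation, and
    MAF-matched fold-enrichment statistics with delta-method confidence
    intervals. A synthetic-data module generates trajectory-structured
    references, pseudo-bulk mixtures with known state abundances, and
    genotypes with planted interactions for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    splines,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, SingleCell, RNASeq, GeneExpression,
    StatisticalMethod, Regression
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'config.R'
    'reference-prep.R'
    'lmm-core.R'
    'reml.R'
    'deconvolve.R'
    'eqtl.R'
    'group-inference.R'
    'io.R'
    'methods.R'
    'simulation.R'
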