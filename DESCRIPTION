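Package: sparsefold
Title: Restraint-Based 3D Chromatin Modelling from Sparse Capture Hi-C Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs ensembles of 3D chromatin models of genomic
    regions from sparse chromosome-conformation-capture interaction
    matrices such as promoter capture Hi-C. Provides the PRINT
    (PRoportion of INTeraction) normalization for capture bias,
    interaction-network based region selection around a viewpoint,
    encoding of normalized interaction frequencies into harmonic and
    lower-bound spatial restraints, steered Langevin dynamics of a
    bead-spring (Kremer-Grest) polymer with time-ramped restraint
    springs, and ensemble validation and comparative statistics:
    model-derived contact maps, particle-to-particle median distance
    correlation (ppMdC), distance RMSD clustering, radial 3D enrichment
    of chromatin marks, and spatial communities of expressed genes.
    A synthetic toy-genome benchmark quantifies reconstruction
    efficiency as a function of capture sparsity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    IRanges,
    S4Vectors,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
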