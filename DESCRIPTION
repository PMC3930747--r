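Package: sectordyn
Title: Protein Plasticity from Trajectory Essential Dynamics and
    Statistical Coupling Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies protein plasticity from molecular-dynamics
    trajectories and multiple sequence alignments, motivated by peptide
    loading in major histocompatibility complex (MHC) class I molecules.
    Provides per-residue backbone phi-dihedral flexibility via circular
    statistics, mass-weighted essential dynamics (trajectory principal
    component analysis) with mode projection, reconstruction and
    block-RMSF stability checks, Gibbs free-energy landscapes over the
    top two principal coordinates with watershed minima and barrier
    detection, and statistical coupling analysis (SCA) of a heavy-chain
    alignment: Kullback-Leibler positional conservation, a
    conservation-weighted positional correlation matrix, eigenmode
    significance against column-randomized alignments, independent
    component analysis, and Student-t tail sector definition with
    structural contiguity and polymorphism overlays. Synthetic-data
    generators produce trajectories with planted collective modes and
    alignments with planted coevolving sectors so every stage is
    testable without undeposited simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    MASS,
    igraph,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
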