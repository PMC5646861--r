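Package: SumoNMR
Title: NMR Titration, Relaxation, Ensemble and Motif Analysis for SUMO-Like Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative NMR characterisation of small
    ubiquitin-like modifier (SUMO) family proteins and their peptide ligands.
    Computes amide chemical shift perturbations (CSP) from Sparky-style peak
    lists, maps binding interfaces with a mean plus two standard deviation
    cutoff, and fits dissociation constants with the quadratic 1:1
    bound-fraction model. Fits per-residue 15N T1/T2 relaxation times by
    mono-exponential decay and computes steady-state heteronuclear NOE ratios.
    Superposes multi-model structure ensembles (Kabsch), reports RMSD-to-mean
    statistics and per-residue RMSF, performs alignment-guided cross-structure
    superposition, and classifies NOE distance restraints by sequence
    separation. Scans protein sequences for SUMOylation consensus sites
    (psi-K-x-E) and SUMO-interacting motifs (SIM). Seeded synthetic-data
    generators emulate fast-exchange titrations, exponential relaxation decays
    and coordinate ensembles with rigid cores and flexible tails, supporting
    parameter-recovery validation of every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    bio3d,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
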