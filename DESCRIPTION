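Package: chamscope
Title: Conformational Ensemble Analysis of Molecular Chameleonicity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing multi-conformer ensembles of flexible
    bifunctional molecules such as PROTACs. Computes conformer-level 3D
    descriptors (radius of gyration, Shrake-Rupley solvent-accessible
    surface area partitioned into polar and nonpolar components,
    intramolecular hydrogen-bond counts, fold classification), performs
    RMSD-based clustering with Boltzmann population analysis and
    minimum-energy-conformation identification, builds property-space
    landscapes and quantifies cross-solvent congruence (molecular
    chameleonicity), and deconvolutes NOE distance restraints into
    conformer populations by constrained least squares with r^-6 ensemble
    averaging (NAMFIS-style fitting). Includes a synthetic generator of
    linker-variant PROTAC mimics with solvent-dependent pseudo-energies
    for end-to-end validation against known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    ChemmineR,
    jsonlite,
    pracma,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
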