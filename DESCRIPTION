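Package: wsme
Title: Sequence-Dependent Wako-Saito-Munoz-Eaton Models of Protein Folding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical-mechanics description of two-state protein
    folding-unfolding with the extended (sequence-dependent) Wako-Saito-
    Munoz-Eaton spin model. Builds native contact maps from PDB structures,
    parameterises per-contact interaction energies (Coulomb, Lennard-Jones,
    generalized-Born polar solvation, buried-nonpolar-area solvation), and
    computes exact stretch-factorised partition functions, free-energy
    landscapes over the fraction of native residues, folding barriers,
    melting temperatures and denaturation mid-concentrations. Also provides
    coordinate-ensemble observables (radius of gyration, RMSF, covariance
    and correlation matrices), two-state sigmoid fits of melting curves,
    NMR chemical-shift-perturbation profiles, and deterministic synthetic
    data generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
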