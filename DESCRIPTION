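Package: mfccpocket
Title: Per-Residue Protein-Ligand Interaction Energies by Molecular
    Fractionation with Conjugated Caps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes the binding energy of a protein-ligand complex into
    per-residue contributions using the molecular fractionation with
    conjugated caps (MFCC) scheme: each binding-pocket residue is excised
    together with its two covalently adjacent cap residues, cut peptide
    bonds are saturated with hydrogens, crystallographic waters are
    attached to their hydrogen-bonded residues, and the interaction energy
    is recovered from a four-term fragment combination. Includes radial
    shell selection of pocket residues with a total-energy convergence
    criterion, a classical pairwise (Coulomb + Lennard-Jones, uniform
    dielectric) energy backend for desk-scale work, an input-deck writer
    and log parser for external Gaussian-style density-functional engines,
    residue ranking and ligand-region contact annotation, and a seeded
    synthetic complex generator with brute-force oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
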