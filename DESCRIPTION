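Package: btbdimer
Title: Binding-Energy, Interface and Co-Expression Analysis of BTB Domain Dimers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether zinc-finger-and-BTB (ZBTB) transcription
    factor BTB domains prefer homo- or heterodimerization. Implements MM-GBSA
    binding free-energy decomposition from per-frame trajectory energy records
    with standard errors and per-residue normalization, heterodimer-preference
    scoring against the homodimer average, salt-bridge occupancy barcodes at a
    3 Angstrom heavy-atom cutoff, Shrake-Rupley solvent-accessible and buried
    surface area series, Calpha RMSD series with equilibration-window
    detection, Kabsch superposition and pairwise RMSD matrices, lineage
    stratified co-expression correlation, ortholog-clade selection on rooted
    phylogenies, and seed-deterministic synthetic-data generators that plant
    known occupancies, energy deltas, correlations and clades for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
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
    utils
Suggests:
    Biostrings,
    bio3d,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
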