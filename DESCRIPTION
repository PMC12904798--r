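Package: qsbench
Title: Benchmarking Scores for Macromolecular Complex Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully automated benchmarking suite to compare predicted
    macromolecular complexes (protein, RNA and DNA polymers plus
    small-molecule ligands) against reference structures. Implements
    sequence-based chain grouping, the QSMap and QSMapR chain-mapping
    algorithms, a reference LDDT implementation with backbone and
    interface variants, quaternary-structure and interface scores
    (QS-score, ICS/IPS, the DockQ family, GDT, RMSD) and
    symmetry-corrected ligand scores (BiSyRMSD, RMSD-LP, LDDT-LP,
    LDDT-PLI) with coverage-aware ligand assignment. Ships a
    deterministic synthetic-structure generator used throughout the
    test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    ChemmineR
Config/testthat/edition: 3
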