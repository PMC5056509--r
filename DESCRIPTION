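Package: vhhscreen
Title: In Silico Screening of Nanobody Variant Yields from Conformational
    Ensembles and Docking Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processes molecular-dynamics conformational ensembles of
    single-domain antibodies (nanobodies, VHHs) into predicted aggregation
    hotspots and aggregates whole-molecule docking scores into a usable-yield
    classification against a wild-type reference. Provides PDB structure and
    multi-model trajectory handling, Kabsch superposition, RMSD/RMSF and
    beta-sheet order parameters, gromos conformational clustering with an
    RMSF-gated backbone selection, residue-residue contact-area maps and the
    per-residue difference-contact statistic, Shrake-Rupley solvent-accessible
    surface areas with a hydrophobic-exposure gate, surface-patch grouping,
    dimer-combination enumeration, docking-cluster selection and the
    five-lowest-score yield verdict, plus seeded synthetic fixture generators
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
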