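Package: pharmscreen
Title: Pharmacophore Modeling and Decoy-Aware Virtual Screening for
    JAK-Family Kinases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Declarative 3D pharmacophore models (hydrogen-bond donors and
    acceptors, hydrophobic contacts, aromatic rings, exclusion volumes),
    ligand feature perception, geometric feature matching by rigid
    least-squares superposition, activity-threshold dataset curation for
    the four Janus kinases (JAK1, JAK2, JAK3, TYK2), and decoy-aware
    enrichment validation (sensitivity, yield of actives, enrichment
    factor, ROC/AUC).  Includes a synthetic benchmark generator that
    plants actives realizing a model within positional jitter alongside
    constraint-violating decoys, so the whole screening pipeline can be
    exercised and validated without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
SystemRequirements: Open Babel (obabel on the PATH); Python 3 with
    RDKit (used by the bundled conformer-embedding helper)
Config/testthat/edition: 3
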