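Package: phore3d
Title: Pharmacophore Hypotheses, Atom-Based 3D-QSAR and Screening
    Enrichment for hERG Affinity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ligand-based prediction of hERG potassium-channel binding
    affinity. Perceives pharmacophore feature sites (acceptor, donor,
    hydrophobic, positive/negative ionizable, aromatic ring), finds common
    k-feature hypotheses across active ligands by tree partitioning of
    inter-site distance space, aligns ligands onto a hypothesis by
    least-squares rigid superposition, fits atom-based 3D-QSAR models
    (binary grid-occupancy descriptors, partial least squares with
    leave-n-out cross-validation), and validates virtual screens with
    enrichment factor, Guener-Henry score, percent yield/ratio of actives
    and ROC/AUC. Includes a deterministic conformer-ensemble generator
    with an energy-window/RMSD retention contract and a synthetic
    benchmark generator (planted pharmacophore, property-matched decoys,
    planted linear activities) so the whole pipeline is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    Matrix,
    igraph,
    jsonlite,
    withr,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    ChemmineOB,
    pROC
Config/testthat/edition: 3
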