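Package: ensplif
Title: Ensemble Protein-Ligand Interaction Fingerprints for Structure-Based
    Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processing of receptor-ensemble docking campaigns with
    per-residue protein-ligand interaction fingerprints (PLIF). Docked poses
    (multi-model AutoDock Vina PDBQT, Tripos MOL2) are fingerprinted with
    seven interaction classes per binding-site residue, aggregated across
    receptors, replicates and binding modes into ensPLIF fraction
    descriptors, and classified with a prior-weighted CART decision tree.
    Includes retrospective-screening statistics (enrichment factor, F1,
    balanced accuracy), docking-score cutoff scanning, model validity checks
    (overfitting, descriptor cross-correlation, y-scrambling), binding-site
    residue selection with docking-box computation, and deterministic
    synthetic-fixture generators for planted-interaction complexes and
    screening tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    rpart,
    withr,
    jsonlite
Config/testthat/edition: 3
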