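Package: nephroSA
Title: Structural-Alert Mining and Evaluation for Drug-Induced Nephrotoxicity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mines structural alerts for drug-induced nephrotoxicity from
    binary substructure-key fingerprints by positive-rate and Fisher-score
    filtering, screens compound sets with the mined alerts, and evaluates
    binary toxicity classifiers with a confusion-matrix metric suite (total
    accuracy, sensitivity, specificity, enrichment factor, Matthews
    correlation, ROC/AUC) including simple-average consensus models.
    Also compares molecular-property distributions between toxic and
    non-toxic classes and projects compound sets into a PCA chemical space.
    Ships a bundled catalog of nephrotoxicity alert SMARTS, reads compound
    tables from CSV/SDF/SMILES with salt stripping and deduplication, and
    includes a planted-alert synthetic-data generator so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    ChemmineR,
    ChemmineOB,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
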