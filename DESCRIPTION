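Package: fpair
Title: Pairwise Interface Accuracy Metrics for Multiple Protein Docking
    Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Evaluation of predicted models (decoys) of multi-chain
    protein complexes against a native reference structure.  Implements
    per-chain-pair interface RMSD (iRMSD) with the CAPRI 4 Angstrom
    acceptable-prediction hit criterion, the fpair statistic (the fraction
    of chain pairs with correct mutual orientation), the fraction of
    native contacts (fnat), global C-alpha RMSD after least-squares
    (Kabsch) superposition, RMSD-class assignment, and aggregate
    decoy-set reports.  A synthetic complex and decoy generator builds
    multi-chain poly-alanine assemblies and rigid-body-perturbed decoy
    populations so the whole metric stack can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
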