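Package: ovoloc
Title: Protein Subcellular Localization with a KNN-SVM One-Versus-One Ensemble
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the subcellular localization of eukaryotic proteins from
    Gene Ontology annotations and sequence-derived descriptors. Proteins are
    encoded as block-structured feature vectors combining a binary Gene
    Ontology block (built over a dense renumbering of the annotation
    vocabulary), the amphiphilic pseudo amino acid composition
    (hydrophobicity and hydrophilicity sequence-order correlation factors),
    and 400 dipeptide frequencies. Features are screened by F-score, and a
    one-versus-one ensemble chooses per class pair between a k-nearest
    neighbour and a radial-kernel support vector machine by leave-one-out
    accuracy, fusing the pairwise decisions through a voting system that can
    return multi-location predictions on ties. Includes jackknife evaluation
    with per-class accuracy, Matthews correlation, overall locative accuracy
    and absolute-true accuracy, a grid-search tuner, a deterministic
    synthetic-corpus generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
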