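Package: mseddi
Title: Multi-Scale Drug Embeddings for Drug-Drug Interaction Event Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Multi-class prediction of drug-drug interaction (DDI) events in
    the cold-start (inductive) setting. Drugs are represented at three scales:
    knowledge-graph embeddings learned with the translational model TransE,
    SMILES notation embeddings learned with a CBOW word-embedding model, and
    chemical-structure embeddings from three message-passing graph encoders.
    Three channel networks re-learn the representations of a drug pair, a
    multi-head self-attention layer fuses them, and a linear predictor assigns
    one of the event classes. Includes a synthetic-data generator with planted
    class structure, drug-level cold-start cross-validation, micro-averaged
    AUC/AUPR and macro-F1 evaluation, and a small reverse-mode automatic
    differentiation engine that powers the neural components.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    Matrix,
    ChemmineR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
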