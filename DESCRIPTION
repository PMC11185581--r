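Package: diliNet
Title: Drug-Induced Liver Injury Prediction from Stacked Proxy-Endpoint Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts human drug-induced liver injury (DILI) from chemical
    structure with a two-stage FeatureNet scheme: tree-ensemble models are
    first trained on nine in vitro and in vivo proxy-hepatotoxicity endpoints
    and two plasma Cmax endpoints, and their predictions are then combined
    with structural fingerprints and physicochemical descriptors to train a
    final DILI classifier. Includes a SMILES standardization and
    deduplication pipeline built on OpenBabel, variance-threshold feature
    selection, Butina scaffold-aware train/test splitting, repeated nested
    cross-validation with successive-halving hyperparameter search, Youden-J
    decision thresholds, likelihood-ratio based evaluation along the ROC
    curve, exact additive tree attributions with MACCS substructure
    highlighting, and a synthetic multi-endpoint corpus generator for fully
    self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    ChemmineR,
    ChemmineOB,
    xgboost,
    e1071,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
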