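Package: rvmtox
Title: Consensus QSAR Modelling of Acute Oral Toxicity with Relevance
    Vector Machines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts continuous molecular toxicity endpoints (pLD50-style
    targets, in log[1/(mol/kg)]) from SMILES. Implements sparse Bayesian
    relevance vector machine (RVM) kernel regression with type-II maximum
    likelihood hyperparameter updates, chi-squared/Cramer's V filter feature
    selection, a uniform regressor interface over inverse-distance kNN,
    random forest, support vector and gradient-boosting baselines, consensus
    averaging of model predictions, an ensemble-variance (STD-DM)
    applicability domain, and fragment/scaffold toxicity-alert analysis based
    on SMARTS fingerprints and Murcko frameworks. Molecule handling is built
    on ChemmineR/ChemmineOB (OpenBabel). Seeded synthetic-data generators
    make the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    ChemmineR,
    ChemmineOB,
    randomForest,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
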