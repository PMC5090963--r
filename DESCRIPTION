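Package: cpirank
Title: Drug Indication Prediction and Ranking from Chemical-Protein
    Interactome Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts and ranks therapeutic indications for small molecules
    from chemical-protein interactome (CPI) profiles, i.e. panels of in
    silico docking scores against a library of protein targets.  Builds
    ICD-9 disease and disease-family endpoints from drug-indication label
    tables, trains one L2-regularized logistic classifier per endpoint,
    evaluates under global, drug-centric and disease-centric protocols with
    repeated k-fold cross-validation, converts raw per-endpoint scores into
    cross-endpoint comparable confidences by empirical-Bayes posterior
    normalization, and emits hierarchical ranked indication reports.  A
    synthetic-data generator with planted target-disease associations and a
    Tanimoto-based train/validation leakage filter make every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
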