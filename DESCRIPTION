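Package: informedml
Title: Knowledge-Informed Machine Learning for Clinical Tabular Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating declarative clinical domain knowledge
    (measurement intervals, guideline threshold rules, a causal Bayesian
    network, and composite clinical indices) into every stage of a tabular
    machine-learning pipeline for binary outcome prediction: interval
    discretisation and constraint-based record filtering, Bayesian-network
    imputation of categorical features with clinically motivated
    tie-breaking, causal feature selection, a rule-weighted binary
    cross-entropy loss for neural-network training, rule-partitioned
    decision trees, and rule/model output hybrids (sum-threshold ensembles
    and adherence-guaranteeing output filters). Includes a paired repeated
    stratified cross-validation harness with the Nadeau-Bengio corrected
    t-test, guideline-adherence and data-efficiency analyses, and a
    synthetic cohort generator built on the causal network so the full
    pipeline is testable without any external data. The shipped default
    knowledge base encodes established type-2 diabetes guidelines for the
    Pima Indians Diabetes schema.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rpart,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
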