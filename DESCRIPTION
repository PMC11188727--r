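Package: exposomekg
Title: Knowledge-Graph Link Prediction for Survey-Based Exposome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds heterogeneous knowledge graphs from ontology-annotated
    survey data on diet, environmental exposures, medications, and health
    conditions, and predicts links between female reproductive disorders and
    exposure variables. Survey responses are translated to ontology terms
    (including lexical mapping of free-text answers), merged with ontology
    hierarchies and supplemental crop-chemical and nutrient link tables into
    a single graph, embedded with random walks and a Skipgram model, and
    scored with a random-forest edge classifier. A comparison pipeline of
    random-forest imputation, elastic-net feature selection, permutation
    importance, and multivariable logistic regression produces odds ratios
    with Bonferroni-adjusted significance tiers, and the two result streams
    are reconciled by exact ontology-term matching. A synthetic cohort
    generator with planted exposure-disease odds ratios makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    igraph,
    jsonlite,
    ranger,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
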