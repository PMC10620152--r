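Package: foodgraph
Title: Graph-Based Ingredient Detection and Product Substitution for Consumer Food Catalogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring hidden ingredient dependencies in consumer
    food products and for proposing like-for-like product substitutions that
    avoid a target ingredient. Product catalogs are normalized (stop-word
    removal, Porter stemming), compound ("hierarchical") ingredients are
    detected and decomposed, and two learning substrates are built: an
    undirected brand graph for node classification and a directed
    criteria-valid substitution graph for link prediction. Ships four node
    classifiers (decision tree, gradient boosting, multi-layer perceptron,
    GraphSAGE with a natively implemented mean-aggregator layer), a GraphSAGE
    encoder / inner-product decoder link predictor with per-epoch negative
    resampling, a synthetic catalog simulator with planted brand signal and
    ingredient hierarchies, and a multi-run evaluation protocol reporting
    accuracy and ROC AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    rpart,
    stats,
    tibble,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
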