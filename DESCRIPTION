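Package: negtetrad
Title: Discrete Bayesian Network Analysis of Negative Psychological
    Variables in Competitive Sport
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for discrete Bayesian-network analysis of
    psychometric questionnaire data: Likert item simulation from a
    ground-truth network, factor scoring and Low/High discretization,
    BIC-scored Tabu structure search, conditional-probability-table
    estimation, exact inference by variable elimination, per-node 10-fold
    cross-validated classification metrics (AUC, accuracy, sensitivity,
    specificity), top/node/bottom topology classification, and greedy
    stepwise evidence instantiation that drives a target variable towards
    its maximal posterior probability of being High.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
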