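Package: mirbeam
Title: Discovery of miRNA-mRNA Interactions from Paired Expression and
    Clinical Data by Bayesian Network Scoring and Multiple Beam Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies pairs of miRNAs and mRNAs whose joint expression
    state carries probabilistic dependency with a categorical clinical
    feature (e.g. tumor versus normal tissue, metastasis, or molecular
    subtype) even when each member shows weak or no marginal association.
    Expression matrices are merged by patient, log2-transformed and
    discretized to equal-width bins; candidate parent sets of a discrete
    Bayesian network target node are scored with the Bayesian Dirichlet
    equivalent uniform (BDeu) marginal likelihood; a Multiple Beam Search
    launches a greedy forward/backward search from every predictor and
    pools high-scoring models; surviving miRNA-mRNA pairs are validated by
    the posterior probability of the joint-interaction model against three
    competing models. A synthetic-data generator with planted epistatic
    (XOR-style) interactions makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
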