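Package: cytobn
Title: Categorical Bayesian Network Inference for Cytokine-Hormone Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Learns categorical Bayesian networks from serum analyte panels
    (cytokines and hormones) profiled across in vivo timecourses. Panels are
    z-score normalized and discretized into equal-frequency concentration
    bins; network structure is learned by Tabu search over the BDe score with
    a literature-seed structure prior; edge support is quantified by
    non-parametric bootstrap model averaging with a confidence threshold.
    Includes exact marginal inference with in-silico point-mass perturbation
    (graph surgery or conditioning), a weighted-mean trend heterogeneity test
    with false discovery rate control, directed-edge confusion statistics
    (specificity, sensitivity, F-score) and parent-category network
    complexity for comparing learned networks, plus a synthetic-data
    generator with planted directed acyclic graphs and temporal cluster
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
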