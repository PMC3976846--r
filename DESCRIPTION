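Package: SyndromeSelect
Title: Hierarchical Syndrome Aggregation and Swarm-Based Feature
    Selection for Clinical Symptom Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Aggregates high-dimensional clinical symptom observations
    into syndrome-level features through a three-layer hierarchy
    (symptoms, syndromes, overall positive score), ranks syndromes with a
    combined correlation and leave-one-feature-out relevance score,
    searches the syndrome-subset space with a chaotic binary particle
    swarm optimizer whose fitness is cross-validated least-squares
    support-vector-regression error, and learns discrete Bayesian
    networks over the selected syndromes with exact probabilistic
    inference. Includes a synthetic-data generator emulating the
    structure of Traditional Chinese Medicine observation panels for
    hepatocellular carcinoma, with planted relevant syndromes for method
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
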