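Package: migconn
Title: Resting-State Functional Connectivity Analysis of Chronic and Episodic Migraine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for whole-brain resting-state functional
    connectivity analysis of chronic versus episodic migraine cohorts: motion
    scrubbing and band-pass preprocessing of 4D BOLD data, temporal-concatenation
    group independent component analysis to define network nodes, ridge-regularized
    partial-correlation networks with power soft thresholding and Fisher r-to-z
    edge weights, degree centrality, permutation-based group inference with
    false-discovery-rate correction and covariate adjustment, seed-to-network
    connectivity of hypothalamus, dorsal raphe nucleus and periaqueductal gray,
    and baseline clinical comparisons. Includes a synthetic-cohort generator with
    planted group differences so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
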