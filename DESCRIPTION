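Package: betanet
Title: Task-Evoked Functional Network Topology from Beta-Series Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for characterizing task-evoked functional brain network
    topology from event-related fMRI designs. Estimates trial-level activations
    with the least-squares-separate (LS-S) method, scrubs motion-contaminated
    trials, builds Fisher-z beta-series connectivity matrices, partitions signed
    networks by modularity maximization (Q* with asymmetric treatment of
    negative weights) and multistep consensus clustering, sweeps the structural
    resolution parameter, and tests community- and region-level differences in
    community allegiance between task conditions with Monte Carlo permutation
    nulls. Includes a synthetic-cohort generator with planted community
    structure so the full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml,
    rlang,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
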