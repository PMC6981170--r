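Package: endonet
Title: Attractor Landscape Analysis of Core Endogenous Gene Regulatory
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the multistable dynamics of small core endogenous
    transcription-factor networks. From a signed regulation table the
    package builds a coarse-grained Hill-function ODE model, enumerates and
    classifies its equilibrium states (attractors, transition and
    hyper-transition saddles) by multistart Newton search, derives the
    topological adaptive landscape by integrating trajectories from
    unstable-subspace perturbations of the saddles, cross-checks attractors
    against a dominant-inhibition Boolean network, computes most probable
    transition paths by minimizing a discretized Freidlin-Wentzell action,
    and matches predicted binary cell-state patterns against single-cell
    expression matrices. Ships the eight-factor pancreatic lineage network
    as the canonical example together with a negative-binomial synthetic
    single-cell generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
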