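Package: posturenet
Title: Postural Sway Metrics, Phase-Lag Connectomes and Spanning-Tree
    Network Integration for Balance-Training Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for balance-skill transfer
    experiments: center-of-pressure posturography (root-mean-square sway,
    95% confidence-ellipse area, Welch mean frequency, sample entropy),
    EEG preprocessing (broadband filtering, ocular-artifact regression,
    epoching, artifact rejection, sub-band filtering), phase-lag based
    functional connectivity (PLI and weighted PLI), minimum-spanning-tree
    network integration metrics (diameter, leaf fraction, average
    eccentricity, maximal betweenness), and the paired statistics used to
    compare sessions (paired t, Hotelling's T-squared with Wilks' lambda,
    Simes post-hoc control). Includes a synthetic-data module generating
    EEG, EOG, and sway trajectories with known ground truth so every stage
    has a recovery test.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    MASS,
    stats,
    utils,
    yaml,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
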