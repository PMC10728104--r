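Package: burstnet
Title: Burst-Level Network Analysis and Simulation for Microelectrode Array
    Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for spontaneous activity of cultured neuronal
    networks recorded on microelectrode arrays (MEAs): adaptive spike detection,
    burstlet and global-burst detection, Fano factor and pairwise synchrony of
    firing, cross-correlation functional connectivity with weighted graph
    efficiency, sparse point-process Granger causality over binary burstlet
    trains (logistic GLM estimated by orthogonal matching pursuit with
    deviance-difference inference and FDR control), marked point-process
    inference of higher-order synchrony, and Tokeshi's test of bimodality.
    Includes a conductance-based leaky integrate-and-fire network simulator with
    spike-timing-dependent plasticity, distance-dependent wiring, glutamate
    injury and BDNF recovery perturbations, pseudo-MEA conversion, and surrogate
    generators with known ground truth for calibrating every analysis stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
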