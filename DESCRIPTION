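Package: netsym
Title: Symmetry and Asymmetry Statistics for Weighted Neural Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies reciprocity in weighted directed neural connectivity
    matrices with a single symmetry measure on connection pairs, provides its
    analytic null distribution under uniform or truncated-Gaussian synaptic
    weights with random pruning, a z-score significance test, motif
    classification into bidirectional and unidirectional pairs, an
    eigenvalue-based comparator, network ensemble generators, and a leaky
    integrate-and-fire network simulator with escape noise and triplet
    spike-timing-dependent plasticity for studying how stimulation protocols
    drive connectivity toward symmetry or asymmetry.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, jsonlite, pracma, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'netsym-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'io.R'
    'cli.R'
    'core.R'
    'null-stats.R'
    'generators.R'
    'inference.R'
    'simulator.R'
    'spectral.R'
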