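Package: burstgf
Title: Generating-Function Solvers and Inference for Stochastic
    Transcription Models in Single-Cell Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Solves chemical master equation models of stochastic
    transcription (constitutive, monomolecular, telegraph, gamma
    Ornstein-Uhlenbeck, Cox-Ingersoll-Ross, bursty, autocatalytic, and
    two-gene co-regulation motifs) by applying the method of
    characteristics to their probability generating functions, and
    inverts the generating functions to count distributions with the
    fast Fourier transform.  Composable technical-noise transforms
    describe droplet encapsulation, ambient background, cDNA library
    construction and read-identity ambiguity in droplet-based
    single-cell RNA sequencing.  Snapshot sampling from transient
    processes is modelled through reactor internal-age distributions
    with a quadrature-recycling batch evaluator.  Includes exact
    stochastic simulation of time-dependent bursty transcription,
    synthetic droplet-dataset generation, likelihood-based parameter
    inference, Akaike-weight model selection, and empty-droplet
    quality-control diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Matrix,
    methods,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
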