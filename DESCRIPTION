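Package: lipmaps
Title: Driving a Biomechanical Lip Model with Surface-EMG-Derived Muscle
    Activation Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for controlling a reduced finite-element model
    of the perioral soft tissue with muscle activation patterns derived from
    multi-channel facial surface electromyography (sEMG). Provides a seeded
    synthetic-data generator (amplitude-modulated band-limited sEMG with
    configurable cross-talk, plus reference lip-marker trajectories), Willison
    amplitude feature extraction with min-max normalisation, mapping of seven
    bilaterally measured facial muscles onto twenty model muscles under three
    activation strategies, a hexahedral Mooney-Rivlin soft-tissue model with
    transversely isotropic muscle fibres and soft incompressibility,
    PCA/cross-correlation temporal alignment of simulated and measured marker
    trajectories, and 3D correlation-coefficient evaluation with grouped
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
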