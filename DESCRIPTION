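Package: glusense
Title: Simulation and Analysis Toolkit for Glutamate Indicator Imaging
Version: 0.1.0
Authors@R:
    person("glusense", "developers", email = "glusense@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing fluorescence recordings made with
    genetically encoded glutamate indicators (iGluSnFR-family sensors):
    spike-triggered-average transient fitting with a rise/decay exponential
    model, autocorrelation-based decay estimation, detection and scoring of
    spontaneous single-vesicle release events ("optical minis") including a
    Poisson-calibrated pixelwise activity statistic and seeded non-negative
    factorization, orientation-tuning statistics with cross-validated
    pixel-pair covariance measures of spatial signal spread, spatiotemporal
    receptive-field estimation from sparse-noise stimuli by
    Laplacian-regularized ridge regression with circular-shift permutation
    significance, generalized linear modelling of combinatorial mutagenesis
    screens with epistatic interactions and bootstrap confidence intervals,
    and fiber-photometry preprocessing with peri-event time histograms.
    Includes a synthetic-data generator emulating photon shot noise,
    diffraction-limited synaptic footprints, indicator kinetics,
    photobleaching and the relevant stimulus designs, so every stage is
    testable against embedded ground truth without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
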