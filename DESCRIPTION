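Package: oscbrain
Title: Whole-Brain Oscillatory Network Models with Regional Heterogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and fitting of whole-brain network models operating in
    the oscillatory regime: a phenomenological Stuart-Landau (Hopf normal form)
    model and an exact mean-field reduction of coupled excitatory-inhibitory
    populations of quadratic integrate-and-fire neurons, both coupled through a
    structural connectome and modulated by a per-region heterogeneity map via
    bias and scale parameters. Includes band-pass filtering and analytic-signal
    phase extraction for BOLD time series, Kuramoto order parameter, functional
    connectivity and global brain connectivity fit statistics, a causal-ignition
    statistic based on Gaussian conditional transfer entropy with circular-shift
    surrogate testing, spatial-autocorrelation-preserving surrogate maps, a
    Balloon-Windkessel hemodynamic transform, synthetic connectome and BOLD
    generators, and a grid-search fitting pipeline with iso-error curve
    extraction and repeated-run model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    signal,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    ape,
    jsonlite
Config/testthat/edition: 3
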