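Package: kinfault
Title: Kinetic-Model-Based Fault Localization in Signalling Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies which single reaction rate constant or preexisting
    molecule of a signal-transduction kinetic model was up- or downregulated,
    given a noisy sampled time course of designated pathway outputs. Candidate
    single-target perturbations are scanned over a grid of fold changes, each
    simulated with a stiff ODE solver, and ranked by a similarity score that
    combines profile shape and magnitude; oscillation features (amplitude,
    period, peak-pair count and the derived R and A factors) confirm near-ties
    for oscillatory outputs. Includes two reduced mass-action demo models (a
    JAK-STAT/SOCS steady-state responder and an NF-kB-style two-feedback
    oscillator), a generator of artificial clinical data with
    signal-proportional Gaussian noise, SBML import/export, and noise- and
    density-robustness experiment sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
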