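Package: spineRD
Title: Stochastic Reaction-Diffusion Simulation of Dopamine-Activated PKA
    Signaling in Spiny Dendrites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mesoscopic stochastic (tau-leap) and deterministic (mass-action
    ODE) simulation of the cAMP/PKA/DARPP-32 signaling network of striatal
    medium spiny neuron dendrites with spines. Provides the full reaction
    network with unit-correct rate handling, subvolume meshes with diffusion
    couplings, anchoring configurations for adenylate cyclase, PKA and
    phosphodiesterase pools, phasic dopamine / calcium tetanus / bath clamp
    stimulation protocols, and the downstream readouts: window-averaged
    phosphoprotein levels, fold changes, percent GluA1 phosphorylation,
    exponential spatial-gradient fits, and the cAMP-vs-colocalization
    activity regression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    deSolve,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
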