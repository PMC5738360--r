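Package: chacha
Title: Rate Models and Parameter Recovery for CRISPR ChaCha GPCR Reporters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action rate models of GPCR-coupled CRISPR effector release
    ("ChaCha" architecture) and doxycycline-inducible dCas9-VPR reporter
    induction. Provides closed-form steady-state algebra, stiff ODE simulation
    under piecewise-constant ligand schedules, seeded synthetic flow-cytometry
    style datasets, bounded multi-start nonlinear least-squares estimation of
    the per-receptor effector stoichiometry and Hill dose-response parameters
    (EC50), and delta-delta-Ct qPCR relative-expression quantification with
    Ct clamping.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
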