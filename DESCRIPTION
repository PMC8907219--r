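Package: chondronet
Title: Semiquantitative Regulatory-Network Modeling of Chondrocyte Biochemical Regulation
Version: 0.1.0
Authors@R:
    person("Maintainer", "Chondronet", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds signed directed regulatory networks of secreted molecules
    (cytokines, growth factors, proteases, structural proteins), transforms
    them into a bounded continuous dynamical system via a normalized
    activator/inhibitor input function and a sigmoid-minus-decay ordinary
    differential equation, and computes steady states under clamping
    perturbations. Provides quantitative model evaluation (normalized mean
    absolute deviation, normalized root squared error, log-shifted absolute
    mean difference), qualitative behavior scoring, genetic-algorithm topology
    calibration against perturbation-response datasets, canned osteoarthritis
    induction and autologous-conditioned-serum treatment scenarios with
    significance gating, a synthetic ground-truth data harness, and a
    command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
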