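Package: dpbnsim
Title: Voxel-Based Simulation of Dose Painting by Numbers in Hypoxic Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiscale in-silico study of biologically adapted radiotherapy for
    hypoxic head-and-neck tumors. Provides an oxygen-dependent linear-quadratic
    cell survival model with oxygen enhancement ratios, a reaction-diffusion
    tumor oxygenation model condensed to per-voxel 16-bin pO2 histograms, a
    voxel-based tumor response model (proliferation, angiogenesis, vascular
    remodelling, stochastic radiation kill, dead-cell resorption, cell
    exchange), generators for virtual tumors with controlled density and
    vascular-fraction heterogeneity, constrained 2 Gy-mean dose redistribution
    optimizers (survival-minimizing and heterogeneity-minimizing objectives),
    adaptive fractionation schemes, and tumor control probability statistics
    (logistic D50 with bootstrap uncertainty and treatment gain).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
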