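Package: tmesim
Title: Hybrid Agent-Based Simulation of Macrophage-T Cell-Tumor Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-scale, hybrid agent-based model of early tumor growth in a
    two-dimensional tissue slice. Discrete cancer cells, macrophages and T cells
    interact on a single-occupancy lattice coupled to reaction-diffusion fields
    for a tumor-derived macrophage activation factor, IL-4 and IFN-gamma.
    Macrophage M1/M2 polarization is decided by a small neural-network surrogate
    trained on a mechanistic differentiation model, enabling fast simulation of
    three macrophage-directed immunotherapies (depletion, recruitment inhibition
    and PI3K-inhibition reeducation) under continuous or cycled schedules, with
    replicate orchestration, treatment sweeps and Latin hypercube sensitivity
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    nnet,
    lhs,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
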