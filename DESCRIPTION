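Package: osteosim
Title: Agent-Based Multiphysics Simulation of Trabecular Bone Remodeling
    Under Denosumab Treatment and Discontinuation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A micro-multiphysics agent-based (micro-MPA) simulator of
    trabecular bone remodeling on a voxel lattice. Couples a hexahedral
    micro-finite-element solver for effective strain, reaction-diffusion-decay
    of the RANK/RANKL/OPG signaling system (including denosumab binding and
    dosing), and stochastic bone-cell agents (osteoclast and osteoblast
    lineages, osteocytes, osteomorphs) that resorb and form tissue. Includes
    synthetic rod/plate trabecular phantom generation, static and dynamic
    morphometry per ASBMR nomenclature, four mechanistic-hypothesis toggles
    (gate-blocking, osteomorph recycling, clast-blast coupling, mechanostat),
    a 16-run factorial driver, and a mixed-effects evaluation layer with
    MAAPE and windowed R-squared comparison metrics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    lme4,
    RNifti,
    tiff
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    Matrix
Config/testthat/edition: 3
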