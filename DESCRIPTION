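Package: gliovox
Title: Stochastic Voxel-Based Simulation of Glioma Growth in a
    Resource-Structured Brain Microenvironment
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates glioblastoma growth and invasion on a voxelized 2D
    brain lattice with multi-clone ploidy dynamics, a metabolic switch
    between oxidative phosphorylation and glycolysis, stochastic voxelwise
    angiogenesis, linear-quadratic radiotherapy with an oxygen enhancement
    ratio, temozolomide and surgery effects, and stiffness- and
    glucose-dependent conservative cell migration. Includes transforms that
    turn imaging-derived maps (SUVr, oxygen extraction fraction, vascular
    area fractions) into resource atlases, a synthetic-atlas generator, a
    three-compartment model of transwell migration assays with rate
    fitting, simulation-based parameter estimation, and reproducible
    NIfTI/CSV/JSON input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
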