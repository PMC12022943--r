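Package: memperm
Title: Membrane Partition, Exchange Kinetics, and Permeation Free-Energy
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of passive membrane transport of large
    amphiphilic solutes. Fits the simple-partition model to fluorescence
    titrations against liposomes and compares partition coefficients across
    conditions; fits mono- and biexponential models to FRET-based
    inter-vesicle exchange traces with a chi-square-halving model-selection
    rule, amplitude-weighted rate constants, and Arrhenius analysis; computes
    Foerster radii from spectral overlap; derives bilayer-trajectory
    descriptors (transverse collective variables, tilt, depth free-energy
    profiles, geometric hydrogen bonds, acyl-chain order parameters,
    instantaneous dipole moments); and post-processes well-tempered
    metadynamics hills into two-dimensional free-energy surfaces with
    replicate averaging and symmetrization, zero-temperature string-method
    minimum free-energy paths, one-dimensional projections, and
    desorption/translocation barrier estimates. Includes seeded synthetic
    generators for every input so the full pipeline is testable without
    instruments or simulation engines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
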