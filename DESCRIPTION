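Package: perfuseed
Title: Perfusion Bioreactor Design: Scaffold Flow, Cell Seeding and PET
    Homogeneity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale in-silico pipeline for designing perfusion
    bioreactors that seed cells into porous bone-substitute scaffolds.
    Generates voxelized porous scaffold volumes with controlled porosity,
    builds full reactor domains (cylindrical or conical diffuser
    connectors, optional lateral encasement, lengthwise or transverse
    orientation), solves steady creeping Stokes-Brinkman flow on a
    staggered grid, scores flow homogeneity with the Hoover (Robin-Hood)
    coefficient over cross-sectional planes, simulates Lagrangian cell
    transport, adhesion and washout under unidirectional or oscillating
    perfusion, and synthesizes dynamic PET-like activity images with ROI
    time-activity and homogeneity readouts. Includes study runners for
    connector-geometry sweeps, seeding-efficiency sweeps and
    configuration comparisons with basic statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    stats,
    utils,
    rlang,
    tibble,
    dplyr,
    tidyr,
    purrr,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
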