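Package: memlens
Title: Trajectory Analysis of Nanoparticle Aggregation in Coarse-Grained Lipid Bilayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for coarse-grained membrane simulations of
    fullerene-loaded lipid bilayers. Reads multi-frame GRO-dialect
    trajectories with an explicit bead-group topology map and computes
    membrane dimensions (area and volume per lipid, bilayer thickness, area
    compressibility from box-area fluctuations), mass density profiles along
    the bilayer normal, nanoparticle cluster statistics under a
    center-of-mass distance criterion with periodic boundaries, radial
    distribution functions and their Boltzmann-inversion free-energy
    profiles, finite-difference entropy/enthalpy decomposition from
    simulations at three temperatures, second-peak split detection,
    inter-particle axis densities, and lateral/normal diffusion coefficients
    from mean-squared displacements. Ships synthetic slab-membrane,
    Metropolis Monte Carlo and Brownian-dynamics generators with closed-form
    ground truths so every stage is testable without a molecular-dynamics
    engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
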