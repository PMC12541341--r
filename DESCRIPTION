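Package: pairfes
Title: Free-Energy and Structural Analysis of Ion Pairing from
    Enhanced-Sampling Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct and analyse free-energy surfaces of ion
    association in water from biased (on-the-fly probability enhanced
    sampling, OPES) simulations, aimed at calcium carbonate ion pairing.
    Provides seeded toy generators (overdamped Langevin dynamics on model
    pair potentials, Brownian diffusion, two-state residence kinetics,
    layered interfaces, committee force sets), OPES-style adaptive biasing
    with harmonic walls, umbrella-sampling-type reweighting onto free-energy
    grids, entropy-corrected radial potentials of mean force with
    short-range and screened-Coulomb tail alignment, standard-state ion
    association free energies, minimax barriers and basin analysis on
    gridded landscapes, structural and dynamical observables (radial
    distribution functions, coordination numbers, electron-density
    profiles, Einstein diffusion with finite-size extrapolation, residence
    times, lattice constants), and periodic electrostatics of spherical
    Gaussian charges at nuclei and Wannier centroids with a direct-sum
    oracle. Readers and writers for extended-XYZ trajectories, COLVAR-style
    collective-variable tables and gridded free-energy text files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
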