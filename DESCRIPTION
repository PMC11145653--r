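Package: excitonkit
Title: Exciton Hamiltonians, Spectral Densities, Lineshapes and Wave-Packet
    Dynamics for Light-Harvesting Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the excitonic analysis of pigment-protein complexes
    such as the minor plant antenna complex CP24: parsing and diagonalizing
    Frenkel exciton Hamiltonians, TrEsp transition-charge couplings with
    distance-dependent dielectric screening, bath spectral densities from
    site-energy fluctuation time series, secular-Redfield and second-order
    cumulant absorption and fluorescence spectra, ensemble-averaged
    wave-packet (NISE) exciton population dynamics over a fluctuating
    Hamiltonian, and structural descriptors (Mg coordination, RMSF,
    PCA/K-means frame selection). A synthetic-data module generates
    Gaussian site-energy fluctuation trajectories with prescribed spectral
    structure and toy chlorophyll-like geometries so that every pipeline
    stage runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
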