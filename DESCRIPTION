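Package: latticerock
Title: Rigid-Body Rocking Motion of Proteins in Crystal Lattices from
    Trajectories and Solid-State NMR Relaxation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise the overall rigid-body ("rocking") motion of
    protein molecules in crystal lattices. Generates synthetic multi-copy crystal
    trajectories with known rigid-body and internal dynamics; extracts per-molecule
    rotation-matrix series by least-squares superposition and computes isotropic
    rocking correlation functions with bi-exponential-plus-base fits; computes
    per-residue NH order parameters, correlation functions, spectral densities and
    15N R1 rates; models 15N R1rho under magic-angle spinning with an on-resonance
    spin-lock via Redfield theory and via a numerical two-site-jump spin propagator
    valid outside the Redfield regime, including rate surfaces and two-branch
    correlation-time solving; fits relaxation decays with Monte-Carlo errors and
    REDOR dipolar dephasing curves by grid chi-square search; and computes crystal
    packing metrics (Matthews coefficient, solvent content).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
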