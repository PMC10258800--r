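Package: solvnoe
Title: Intermolecular NOE Cross-Relaxation and Preferential Solvation from
    Molecular Trajectories
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes intermolecular 1H-19F dipolar correlation functions,
    spectral densities, and cross-relaxation rates (Sigma_HF) for a peptide
    hydrogen relaxed by solvent fluorines, from molecular coordinate
    trajectories.  Includes a synthetic Brownian-dynamics generator with a
    reflecting model solute, DISCRETE-style multi-exponential fitting of
    correlation functions, the analytic Ayant/Hwang-Freed force-free
    hard-sphere model as an independent oracle, solvation-shell occupancy
    and solvent-contact persistence statistics, bulk and distance-resolved
    translational diffusion estimators, and fluoroalcohol cluster analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
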