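Package: allokin
Title: Free-Energy, Kinetics and Functional-Mode Analysis of Catalyzed Torsional Isomerization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dissecting how free-energy barriers and
    reaction-coordinate diffusion jointly set a catalyzed torsional
    isomerization rate. Provides Brownian-dynamics generation of restrained
    (umbrella) and unrestrained torsion-angle trajectories on periodic
    dihedral potentials with scaled barriers, weighted-histogram (WHAM)
    free-energy profiles with Monte Carlo bootstrap errors, superposition and
    first-order cumulant extrapolation of profiles measured at reduced
    barriers to the unmodified potential, Kaplan-Meier survival kinetics of
    barrier crossing with confidence-interval-weighted exponential fitting,
    estimation of the effective diffusion coefficient by fixed-slope Kramers
    regression with first-order error propagation, and detection of
    function-correlated collective motions in pooled conformational ensembles
    by multiensemble PCA and partial-least-squares functional mode analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    survival,
    pracma,
    bio3d,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
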