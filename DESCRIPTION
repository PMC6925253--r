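Package: rockbundle
Title: Coarse-Grained Rocking-Bundle Dynamics of Ion-Coupled Transporters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds and simulates a coarse-grained (C-alpha level) model of a
    LeuT-fold secondary transporter whose outward-facing and inward-facing
    states are related by a rigid-body rocking of one four-helix bundle
    against the other, with an ion pseudo-particle bound at the bundle
    interface by five harmonic distance restraints. Provides a double-basin
    elastic-network energy model, overdamped Langevin equilibrium and steered
    dynamics with exact nonequilibrium-work bookkeeping and a Jarzynski
    estimator, the collective variables used to drive and monitor the
    transition (center-of-mass distances, radii of gyration, RMSD after
    optimal superposition, orientation quaternions), completion detection via
    gating-residue radii of gyration, and trajectory analyses including
    residue-correlation network analysis and bundle-relative RMSD, together
    with a reproducible end-to-end pipeline comparing ion-bound and apo
    conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    igraph,
    bio3d,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
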