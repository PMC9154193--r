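Package: nksynapse
Title: Spatial Kinetic Monte Carlo Modeling of NK-Cell Synapse Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatially resolved stochastic simulation of membrane-proximal
    signaling at the natural killer (NK) cell immunological synapse. Implements
    a chambered-lattice kinetic Monte Carlo model of activating NKG2D/DAP10 and
    inhibitory KIR2DL2 receptor signaling, phospho-Vav1 driven microcluster
    formation and centripetal transport, two-point correlation quantification
    of spatial receptor patterns, and particle swarm optimization of kinetic
    and spatial parameters against target intensity fields, with uncertainty
    quantification via intrinsic-noise cost ensembles and density-peak
    clustering. Includes scenario drivers for ligand-rebinding decay assays,
    clustering ablations, and inhibitory-ligand dose responses, plus a
    synthetic clustered-pattern generator for fitting targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
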