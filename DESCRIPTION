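Package: helixknot
Title: Langevin Dynamics and Knot Analysis of DNA in Helical Nanochannels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained Langevin molecular dynamics of a semi-flexible
    worm-like DNA chain confined in implicit cylindrical or helical
    nano-channels, with piston compression, and a complete observable and
    knot-theoretic analysis suite. The confining wall is implicit: the
    nearest distance from a bead to the helical mid-curve is found by Newton
    iteration, so channel geometry (diameter, helix radius, pitch,
    handedness) enters only through a smooth repulsive wall force. Analyses
    include span and gyration metrics, span histograms and elastic free
    energy, radial monomer distributions and confinement free energy,
    orientational correlations, Odijk and force-law scaling fits, and a
    polymer knot pipeline: chain closure, KMT triangle simplification,
    Alexander-determinant knot typing, Gauss-integral writhe, signed
    crossing counts, average crossing number and knotted-core localization.
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
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
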