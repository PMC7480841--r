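Package: wingsce
Title: Subcellular-Element Mechanics of the Wing Disc Cross-Section
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the cross-sectional mechanics of the Drosophila wing
    imaginal disc with a subcellular-element (SCE) model: nucleus, membrane and
    extracellular-matrix (ECM) nodes moved by overdamped explicit-Euler dynamics
    under Morse and spring potentials, with per-cell area (2D volume)
    conservation. Provides builders for the calibrated flat tissue (columnar
    pouch, marginal boundary cells, squamous layer, three-region ECM chain with
    optional prestrain), declarative perturbation scenarios (patterned ECM
    tension, basal actomyosin contractility, shape maintenance by ECM damping,
    collagenase-like ECM removal, dual perturbation with interlayer-adhesion
    loss), shape quantification (circumcircle global curvature, Menger local
    curvature profiles, fractional apicobasal nuclear position, cell height,
    asymptotic convergence fits), and a Latin-hypercube partial-rank-correlation
    sensitivity screen.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    lhs,
    minpack.lm,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
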