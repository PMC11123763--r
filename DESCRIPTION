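Package: giantspin
Title: Powder EPR Simulation for High-Spin and Giant-Spin Systems with
    Higher-Order Zero-Field Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Field-swept continuous-wave EPR powder-spectrum simulation for
    arbitrary spin S with the complete orthorhombic zero-field interaction up
    to sixth order in the Stevens-operator formalism.  Builds spin
    Hamiltonians from conventional (D, E) parameters or individual Stevens
    constants B_k^q, locates resonance fields by eigenvalue bracketing over a
    deterministic equal-solid-angle orientation grid, and produces
    lineshape-convolved absorption and first-derivative spectra.  Includes
    rhombograms of effective g values for Kramers systems, rhombicity
    distributions, the giant-spin scaling relations used for
    superparamagnetic nanoparticle cores such as ferritin, a
    largest-diagonal-element audit of the non-scalability of higher-order
    terms, and a coefficient switch-on inventory of powder line shapes with
    rule-based spectral feature detection.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
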