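Package: otkinetics
Title: Binding-Kinetics Inference from Optically Trapped Microparticle Signals
Version: 0.1.0
Authors@R: person("Ana", "Ferreira", email = "ana.ferreira@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of optical-tweezers experiments that
    monitor molecular binding in real time. Simulates the Brownian motion of
    a microparticle in a harmonic optical trap whose effective drag grows as
    a ligand monolayer forms on its surface, renders quadrant-photodiode
    detector channels (X, Y, SUM), estimates per-second effective friction
    coefficients by fitting Lorentzians to power spectral densities of the
    SUM-normalized signals, and infers pseudo-first-order association
    kinetics (observed rate constant and association rate constant) from the
    friction-coefficient trajectory via sigmoid fitting. Includes utilities
    for surface-saturation coating calculations and size-exclusion
    chromatography calibration, plus a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
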