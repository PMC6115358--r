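Package: sorpflex
Title: Hybrid GCMC/MD Simulation of Water Sorption in Deformable Nanoporous Polymers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Osmotic-ensemble (mu-sigma-T) simulation of water sorption in soft
    nanoporous polymer hosts by alternating grand canonical Monte Carlo water
    exchange with constant-stress molecular dynamics relaxation of the host.
    Includes a rigid three-site (SPC/E) water model, a bead-spring amorphous
    polymer host builder with hydrogen-bond donor/acceptor decoration, hydrogen
    bond network detection and classification (water-water, host-water,
    host-host), pair-isolation hydrogen bond energies, radial distribution
    functions, stochastic inscribed-sphere pore size distributions, volumetric
    tensile testing with undrained bulk modulus extraction, and adsorption /
    desorption isotherm drivers for studying sorption-induced swelling and its
    hysteresis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
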