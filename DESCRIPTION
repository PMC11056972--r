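Package: neoadapt
Title: Adaptive Nuclear-Electronic Orbital Hartree-Fock with Movable Proton Basis Centers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multicomponent restricted Hartree-Fock engine in which selected
    hydrogen nuclei are treated quantum mechanically alongside the electrons,
    both species expanded in atom-centered Gaussian bases (the nuclear-electronic
    orbital, NEO, ansatz). The centers carrying the quantum-proton basis
    functions are relocated during the self-consistent-field cycle to the
    charge centroids of the occupied nuclear orbitals, so the calculation
    converges to the proton-position-optimized (standard NEO) potential-energy
    surface without gradient-based geometry optimization. Includes a
    McMurchie-Davidson Gaussian integral engine over movable centers, a
    stepwise coupled two-species SCF with DIIS acceleration, a
    numerical-gradient optimizer used as an independent validation oracle,
    one-dimensional potential-energy-surface scans, bundled small-molecule
    fixtures, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
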