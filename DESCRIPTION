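Package: fragpt2
Title: Two-Fragment Active-Space Embedding with Perturbative
    Interfragment Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multireference embedding for molecules split into two active
    fragments. Canonical molecular orbitals are localized (Pipek-Mezey over
    fragment Mulliken populations), recanonicalized and assigned to fragments;
    each fragment's active space is solved exactly (full configuration
    interaction) in the self-consistent mean field of the other fragment,
    yielding the lowest-energy symmetry-respecting product state. Interfragment
    correlation is then recovered by second-order multireference perturbation
    theory in a partially contracted basis, with the interaction decomposed
    into dispersion, single and double charge-transfer, and triplet-triplet
    spin-exchange channels. Includes a built-in Gaussian-integral and
    restricted Hartree-Fock backend, an FCIDUMP interface, seeded synthetic
    two-fragment model Hamiltonians, and brute-force oracles (full CASCI and
    uncontracted second-order perturbation theory) for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pracma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
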