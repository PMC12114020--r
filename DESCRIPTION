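Package: qmmmion
Title: QM/MM Ionization-Energy Decomposition and Hole Analysis for Solvated Nucleotides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for vertical and adiabatic ionization of
    nucleotide-like solutes in explicit water droplets under electrostatic
    embedding. Provides a labeled molecular data model with XYZ/PDB readers
    and writers, distance-based QM-region selection with a convergence scan,
    constrained least-squares fitting of electrostatic-potential (ESP)
    charges on van der Waals shell grids, a fluctuating-charge
    (electronegativity-equalization) surrogate engine that decomposes total
    energies into polarized-QM, QM-MM van der Waals and MM terms, per-snapshot
    vertical/adiabatic ionization energies and released energies in three
    frameworks, component-resolved hole distributions and hole transfer, and
    ensemble statistics (mean, standard deviation, standard error) over
    snapshot sets, together with a deterministic synthetic droplet and
    record generator for desk-scale studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
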