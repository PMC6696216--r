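Package: cdftkit
Title: Conceptual-DFT Reactivity Descriptors for Peptides from
    Quantum-Chemistry Outputs
Version: 0.1.0
Authors@R:
    person("cdftkit", "developers", role = c("aut", "cre"),
           email = "cdftkit@example.org")
Description: Computes global and local conceptual density-functional-theory
    (CDFT) chemical-reactivity descriptors for peptides and other closed-shell
    molecules from the outputs of quantum-chemistry calculations. Frontier
    orbital energies are mapped to ionization potential and electron affinity
    through the Koopmans-in-DFT (KID) approximation, from which
    electronegativity, global hardness, electrophilicity, the electrodonating
    and electroaccepting powers, net electrophilicity, the gap-based maximum
    absorption wavelength and a hardness-based pKa prediction are derived.
    Local reactivity is characterized by condensed Fukui functions, the
    condensed dual descriptor and Parr functions from Mulliken population
    analyses of the neutral, radical-cation and radical-anion states, plus
    volumetric Fukui fields on Gaussian cube grids. Includes parsers for
    Gaussian-style text logs and cube files, a synthetic-data generator for
    offline testing, bundled virotoxin reference fixtures, and a command-line
    front end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
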