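Package: pbdmelt
Title: DNA Melting in Crowded Solution with the Peyrard-Bishop-Dauxois Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes melting profiles of heterogeneous DNA duplexes in the
    presence of inert molecular crowders using the Peyrard-Bishop-Dauxois
    (PBD) lattice model. Crowders are represented as local multipliers on
    the Morse hydrogen-bond depth of the crowded base pair. The
    configurational partition function is evaluated by transfer-integral
    contraction on a Gauss-Legendre grid, yielding free energy, specific
    heat, melting temperature, the fraction of open base pairs, per-site
    opening probabilities, and mean base-pair separations. Includes an
    exhaustive crowder-placement scanner, a synthetic heteropolymer
    generator for long-chain scenarios, and an independent Metropolis
    Monte Carlo sampler of the same Hamiltonian for validation.
License: MIT
Encoding: UTF-8
Imports:
    pracma,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
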