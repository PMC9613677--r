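Package: pbftcell
Title: Cellular-Level Monte Carlo Simulation of Proton Boron Fusion Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates proton irradiation of monolayer cell arrays to assess
    alpha-particle dose enhancement from the p + 11B -> 3 alpha fusion
    reaction (proton boron fusion therapy, PBFT). Builds rectangular-
    parallelepiped cell-array geometries with configurable boron loading of
    cytoplasm, nucleus and buffer medium; transports protons and secondary
    alpha particles with a condensed-history Monte Carlo scheme driven by
    embedded Bethe-type stopping powers and compact reaction-channel cross
    sections (including the boron-free 16O(p,a)13N, 14N(p,a)11C and 12C
    channels); scores per-region and axial energy deposition, alpha hit
    counts, energy-deposition fractions and boron/normal enhancement factors
    with batch statistics; constructs spread-out Bragg peak (SOBP) sources by
    non-negative least squares; and exports PHITS-style input decks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
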