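Package: gacakin
Title: Kinetic Modeling of Promiscuous Dimeric Dinucleotide Cyclases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Mass-action kinetic model of a homodimeric GGDEF-domain
    dinucleotide cyclase (GacA-type) that competes ATP and GTP across two
    half-active sites to produce cyclic di-GMP, cyclic di-AMP and
    3',3'-cGAMP. Implements the 14-species reaction network with
    depletion and substrate-clamped (homeostasis) simulation modes, an
    exact steady-state flux solver, cooperative single-substrate
    initial-rate fitting, grid-search estimation of the heterodimeric
    dissociation constants from product-ratio data, forward prediction
    scans (homeostasis and asymmetric-activation), activation-energy
    conversion, GGDEF signature-motif classification of aligned protein
    sequences, and seeded synthetic-data generators for all of the above.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
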