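Package: prfkin
Title: Kinetic Modelling of -1 Programmed Ribosomal Frameshifting at the
    dnaX Slippery Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a kinetic state-network model of -1 programmed
    ribosomal frameshifting during translation of the Escherichia coli
    dnaX frameshift mRNA.  The unlocked pre-translocation ribosome
    partitions between effective, futile and incomplete (+2)
    translocation by Boltzmann weighting of the free-energy barriers
    set by the downstream hairpin, the internal Shine-Dalgarno (SD)
    interaction and codon-anticodon re-pairing; incomplete translocation
    feeds a long-paused rotated state in which aminoacyl-tRNA and EF-G
    sample the ribosome repeatedly before the pause is resolved.  The
    package provides the closed-form branching probabilities and their
    force-dependent extension, tRNA sampling and EF-G occupancy algebra,
    mean rotated-state lifetimes for the three site classes, an exact
    stochastic (Gillespie) simulator over the declared state networks
    that doubles as a synthetic single-molecule trace generator, and the
    parameter-extraction chain that recovers the kinetic constants from
    observed single-molecule aggregates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
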