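Package: strainsort
Title: Abundance-Aware Re-Assignment of Metagenomic Reads to Reference
    Strains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Re-assigns aligned metagenomic reads to reference genomes at
    strain resolution. Reference abundances are first estimated from the
    alignment scores by an expectation-maximization algorithm over read
    equivalence classes, with a greedy set-cover filter that removes
    redundant low-abundance references. Each read is then re-assigned to
    exactly one reference by a capacity-constrained greedy algorithm,
    modelled on the weapon-target assignment problem, in which each
    reference accepts reads in proportion to its estimated abundance; a
    swap move that provably never increases the assignment objective
    places leftover reads. Includes a score-level synthetic community
    simulator, an exact brute-force minimizer for small instances, and
    rank-aware (strain/species/genus) evaluation metrics. Input is any
    SAM or BAM file with AS alignment-score tags.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rsamtools,
    jsonlite,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
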