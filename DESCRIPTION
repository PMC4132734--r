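Package: iesr
Title: Simulation and Analysis of Internal Eliminated Sequence Retention in Ciliates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide analysis of programmed DNA elimination in
    ciliates such as Paramecium tetraurelia. Provides a synthetic
    germline/somatic (MIC/MAC) genome and read generator with known per-locus
    retention, IES retention scoring (IRS) from junction- and
    boundary-spanning reads, detection and canonical realignment of TA-bounded
    excision errors (TA-indels), scanning for quasi-IESs flanked by perfect
    terminal inverted repeats, sub-terminal base-frequency and
    relative-entropy sequence-logo analytics with a non-uniform background,
    small-RNA (scnRNA/iesRNA) density profiling against retention scores, and
    correlation analyses between retention scores of identical and adjacent
    IESs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
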