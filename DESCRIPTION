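Package: lrprofile
Title: Error Profiling of Long Sequencing Reads
Version: 0.1.0
Authors@R: person("BOKU", "Bioinformatics", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Characterizes the error structure of long sequencing reads
    (Oxford Nanopore, PacBio) aligned to a reference genome. Reconstructs
    per-column edit scripts from SAM CIGAR and MD tags, aggregates
    substitution, insertion and deletion rates and longest-perfect-match
    statistics per read set, computes sliding-window error distributions
    along reads, counts k-mers in circular references and linear read sets
    to detect over- and under-represented k-mers (including homopolymer
    distortion), and compares profiles across raw, patched and corrected
    read sets. Includes a seeded long-read simulator with exact truth
    alignments for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
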