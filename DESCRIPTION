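Package: diplointron
Title: Characterization of Canonical and Noncanonical Introns in Diplonemid-Like Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing spliceosomal introns from split-read
    evidence in draft genome assemblies, motivated by the unusual intron
    landscapes of diplonemid flagellates, where some lineages carry almost
    exclusively noncanonical (non-GT-AG) introns. Provides a split-read
    junction caller with support and strand filtering, canonical versus
    noncanonical splice-site classification, position weight matrix and
    sequence-logo summaries of donor and acceptor sites, YTRAY branch-point
    scanning, a base-pairing statistic between intron (or exon-flank) ends
    computed with a maximum base-pairing dynamic program, UPGMA clustering of
    species splice-site matrices into newick trees, and a fully seeded
    synthetic-data generator producing genomes, annotations, spliced SAM
    reads, and ground truth for canonical-mode and hemistasiid-mode species.
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
    ape,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
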