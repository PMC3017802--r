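Package: organellarch
Title: Organelle Genome Architecture, Repeats, and Bait-and-Walk Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting the architecture of organelle (mitochondrial
    and plastid) genomes of the kind found in chlamydomonadalean green algae.
    Reads annotated GenBank flat files with circular wrap-around support;
    computes coding/noncoding/intergenic/intronic accounting, GC content by
    region and codon position, cumulative GC-skew, intron/gene ratios, and
    gene inventories; detects the large inverted repeat of a plastid genome
    and partitions it into IR/LSC/SSC; finds maximal dispersed repeats
    (forward, reverse, complement, reverse-complement; exact or Hamming-
    approximate), repeat families, and sliding-window dotplots; scans for
    palindromic hairpin elements and their genomic clusters with consensus
    building; reimplements bait-and-walk genome assembly from shotgun trace
    archives (seeded read recruitment, greedy overlap-layout-consensus,
    iterative contig walking, circular closure); and generates fully
    annotated synthetic organelle genomes plus simulated trace archives for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
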