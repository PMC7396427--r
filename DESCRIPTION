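Package: mitocirc
Title: Comparative Analysis of Circular Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative mitogenomics on circular genomes:
    annotation input/output (tab-separated tables, minimal GenBank flat
    files, FASTA), circular feature geometry (gene lengths, intergenic
    spacers, overlaps, noncoding regions and putative control-region
    identification), base composition with AT/GC strand-skew statistics,
    codon counting with relative synonymous codon usage (RSCU) and
    amino-acid usage under explicit NCBI genetic codes, signed circular
    gene-order comparison (conserved block decomposition, breakpoint
    distance, rearrangement-event simulation including tandem
    duplication-random loss), and a seeded synthetic mitogenome generator
    for end-to-end validation. Ships annotation and codon-count tables for
    the sea cucumber Phyllophorus liuwutiensis mitogenome as worked
    fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
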