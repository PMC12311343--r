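Package: isoqpcr
Title: Isoform-Aware qPCR Primer Design from Expression-Ranked Splice Junctions
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Designs and prioritizes qPCR primer pairs that target all
    expressed splicing isoforms of requested genes.  Transcript models are
    built from a genome FASTA and a GENCODE/Ensembl-style GTF, isoforms are
    classified as expressed with a per-gene quantile threshold applied to an
    isoform quantification table (TPM), exon-exon junctions are ranked by
    their prevalence across isoforms, junction-overlapping primer pairs are
    enumerated under standard qPCR constraints with a nearest-neighbor
    melting-temperature model, specificity is screened by mismatch-tolerant
    in-silico PCR against the transcriptome and genome, and surviving pairs
    are scored by the cumulative expression they amplify with a preference
    for ~200 bp amplicons.  Includes a seeded synthetic-locus generator so
    the whole pipeline is testable without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
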