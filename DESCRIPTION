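Package: diskmer
Title: Discriminative k-mer Indexing and Taxonomic Sequence Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds indexes of k-mers unique to user-defined reference targets
    (species or genus groups, chromosome arms) and assigns query sequences
    (reads, contigs, transcripts) to the target sharing the most discriminative
    k-mers, with a confidence score. Provides four speed/accuracy modes (full,
    default, express, light), centromere inference from k-mers shared by the
    two arms of a chromosome, a synthetic-community and read simulator for
    validation, and readers/writers for FASTA, FASTQ, k-mer distribution text
    files, target-definition tables and per-object result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
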