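Package: iesweave
Title: Detection and Analysis of Internally Eliminated Sequences from
    Mapped Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for annotating natural genome editing in ciliates from
    long-read sequencing data. Detects internally eliminated sequence (IES)
    junctions as insertions in reads mapped to a somatic (MAC) genome
    assembly, assembles insert consensus sequences from noisy subreads via
    flank-anchored multiple alignment and realignment, and annotates pointer
    repeats and TA boundaries. Computes per-site and per-read IES retention
    scores against an IES annotation and bins reads into germline-like and
    somatic-like sets. Predicts alternative chromosome breakage sites from
    telomere-repeat-bearing soft clips. Includes a deterministic synthetic
    long-read simulator that emits paired MAC/MIC genomes, reads with tunable
    error profiles, ground-truth alignments, and an evaluator for recall,
    precision and assembly accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    methods,
    Rsamtools,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
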