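Package: telandscape
Title: Transposable Element Landscape Analysis for Compact Fungal Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing and analysis of transposable element (TE)
    annotations in compact (fungal-sized) genome assemblies. Refines raw
    RepeatMasker/GFF3 annotations by joining interrupted fragments,
    subtracting simple repeats and removing sub-threshold hits; dates LTR
    retrotransposon insertions from 5'/3' LTR divergence under a Kimura
    two-parameter molecular clock; detects nests (TEs inserted within TEs)
    and clusters (TEs within 10 kb of each other) and profiles TE density
    along chromosomes; produces genome summary tables of copy numbers, DNA
    amount and composition; builds neighbor-joining phylogenies with
    bootstrap support from reverse transcriptase / ribonuclease H domain
    alignments; and simulates genomes with planted TE copies of known age,
    truncation, nesting and clustering so every stage can be validated
    against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
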