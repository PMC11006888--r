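Package: ribostall
Title: Ribosome Profiling Quantification and Stall-Site Detection for
    Plastid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies chloroplast ribosome-profiling (Ribo-seq) data at
    the level of plastid open reading frames and detects sites of
    ribosome stalling.  Footprint intervals (BED6) are assigned to ORFs
    by their 5' ends, expression is summarised as cpRPKM (reads per
    kilobase of ORF per million reads mapped to all chloroplast ORFs),
    per-ORF coverage profiles are normalised by total gene reads, major
    pause peaks are called at codon resolution, and a replicate-based
    relative peak-height ratio compares mutant genotypes against the
    wild type, gene by gene across the whole plastid genome.  Library
    quality is checked via the footprint length distribution and the
    3-nucleotide periodicity of 5' ends.  A seeded synthetic footprint
    generator with a known pause architecture provides ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
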