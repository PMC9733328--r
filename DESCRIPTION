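Package: cagevol
Title: Evolution of Trinucleotide Repeat-Derived Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how protein-coding sequences arise from
    expanding trinucleotide repeats, modelled on the birth of a rodent
    oocyte gene from an LTR retrotransposon insertion and a (CAG)n repeat.
    Provides exhaustive point-mutation combinatorics of codons and repeat
    reading frames (polyQ/polyS/polyA), detection of eroded repeat tracts
    and per-codon frame classification, spliced-transcript assembly and ORF
    inference from exon models, self-alignment decomposition of coding
    sequences into duplicated blocks, per-position divergence and start-codon
    census statistics for LTR-family alignments, a stochastic generational
    simulator of repeat-locus evolution under substitution, slippage and
    segmental duplication, and seeded synthetic-data generators with planted
    ground truth for every analysis stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
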