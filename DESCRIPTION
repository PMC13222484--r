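Package: haprefine
Title: Haplotype-Aware Refinement of Diploid Genome Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for refining gene annotations of haplotype-resolved diploid
    genome assemblies. Protein models from one haplotype are matched against
    the other, candidate haplotype-specific genes are validated against
    variant consequences (start/stop loss, premature stops, frameshifts,
    splice-site loss), structural-variant overlap and unaligned regions,
    missed genes are rescued by synteny-guided model projection, split and
    merged gene structures are repaired, and transposon-related or putative
    false-positive models are filtered. Companion analyses identify bi-allelic
    gene pairs, classify per-tissue allelic expression states, compute
    tissue-specificity indices, and apply positional and transposon-overlap
    rules for long intergenic non-coding RNAs. A seeded simulator generates
    diploid fixtures (genomes, annotations with planted errors, variants,
    synteny blocks, expression tables) with known truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
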