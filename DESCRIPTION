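Package: refscaf
Title: Reference-Guided Scaffolding of Draft Genome Assemblies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Orders and orients draft-assembly contigs into chromosome-scale
    pseudomolecules using whole-genome alignments (PAF) against a reference
    genome. Each contig is clustered to the reference chromosome it covers
    the most, ordered by its longest (primary) alignment, and oriented by a
    base-pair-weighted strand vote; every placement carries clustering,
    location, and orientation confidence scores. Optional pre-passes detect
    and break inter- and intrachromosomal chimeric contigs from discordant
    alignments while honoring protected gene intervals. After pseudomolecule
    construction, structural variants (insertions, deletions, tandem and
    repeat expansions or contractions) are called from within- and
    between-alignment signals, annotated with their overlap against assembly
    gaps, merged across samples by breakpoint proximity, and summarized as a
    presence/absence matrix and per-gene counts. A simulation module
    partitions any reference into benchmark assemblies of tunable difficulty
    and scores scaffolder output with clustering, ordering (token edit
    distance and adjacent-pair accuracy), orientation, and localization
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    stringi,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
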