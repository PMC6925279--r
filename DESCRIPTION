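Package: polyte
Title: Transposable Element Insertion Detection and Cross-Ploidy Population
    Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects non-reference transposable element (TE) insertions from
    split-read and discordant-pair evidence in short-read alignments, and
    analyses the resulting insertion landscapes across diploid and
    autotetraploid cohorts: carrier-frequency spectra with Hardy-Weinberg
    dosage conversions under polysomy, genomic-compartment classification and
    enrichment tests, stepwise multiple linear models of TE content,
    ploidy-subsampled content comparisons, family-level transposition-burst
    tests, clade-specific insertion classes, carrier/non-carrier expression
    ratios, and a targeted two-reference locus genotyper. A self-contained
    synthetic-data generator (genome, annotation, populations, reads,
    expression) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    yaml,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
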