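Package: recland
Title: Fine-Scale Recombination Landscape Analyses with Constrained
    Permutation Nulls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing fine-scale recombination landscapes from
    interval data: relative hotspot density across meiotic gene-expression
    quantiles, metagene profiles of recombination rate by distance to
    transcription start and end sites, and repeat-family enrichment of
    double-strand-break hotspots assessed against a constrained-shuffle
    permutation null restricted to the callable genome (excluding ENCODE
    blacklist and zero-coverage regions). Includes readers for BED,
    narrowPeak, GTF, bedGraph, UCSC RepeatMasker tables and expression
    tables, a synthetic-data generator with planted ground truth for
    end-to-end verification, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    data.table,
    jsonlite,
    withr,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
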