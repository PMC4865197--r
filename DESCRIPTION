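Package: gapfillr
Title: Headless Gap Closure for Draft Genome Scaffolds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects gaps (maximal N-runs) in draft genome scaffolds,
    ingests contig-versus-scaffold alignments (BLAST tabular, nucmer
    show-coords, or a built-in seed-and-extend aligner), discovers
    same-contig alignments flanking each gap, ranks candidate fills,
    applies accepted fills with a change log, and accounts for gaps and
    Ns before and after closure. Manual curation is supported through a
    reviewable tab-separated candidate file instead of a graphical
    interface. Includes a ground-truth simulator for validating closure
    accuracy and a command-line entry point.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
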