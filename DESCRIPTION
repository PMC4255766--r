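Package: TransloScape
Title: Genome-Wide Characterization of Chromosomal Material Exchange
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the genome-wide characterization of chromosomal
    material exchange from translocated-fragment-pair call sets (BEDPE).
    Provides two-stage false-positive filtering against simple-repeat and
    low-mappability tracks, cohort landscape summaries (fragment sizes,
    per-subject burden, genome coverage, annotation overlap), recurrent
    exchange detection on fixed-width genome bins, occurrence-threshold
    hot-region identification with partner profiling, interchromosomal
    enrichment scores, catalog comparison via cytoband-to-base-pair
    conversion, motif scanning with a brute-force planted (l,d) motif
    search, set-enrichment statistics, and a ground-truthed synthetic
    data generator so the full pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
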