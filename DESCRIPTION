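Package: meibench
Title: Benchmarking, Merging and Cohort Prioritisation of Mobile Element
    Insertion Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-caller analysis layer for mobile element insertion (MEI)
    detection in short-read sequencing data. Normalises heterogeneous MEI
    call sets (VCF, BED, tab-delimited) into a unified model, benchmarks
    predictions against truth sets using target-site-duplication-aware
    breakpoint windows, applies and optimises read-support filters by
    F-score grid search, merges call sets across tools and samples with a
    breakpoint tolerance, runs a rare-disease cohort prioritisation cascade
    (target regions, unaffected-sample exclusion, known-polymorphism
    exclusion, carrier-frequency and gene-panel filters), and computes
    diagnostic-yield statistics. Includes a synthetic call-set and cohort
    simulator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
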