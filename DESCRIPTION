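Package: repliid
Title: Quantification of Pooled Barcode ChIP Screens for Replisome Occupancy
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scoring pipeline for pooled barcode-sequencing screens that read
    out DNA polymerase occupancy at a barcoded replication origin by ChIP
    (Repli-ID). Turns raw barcode-amplicon FASTQ reads from IP and input
    samples into per-mutant occupancy scores via an input-abundance filter,
    median normalization, IP/input ratios, replicate averaging and log2
    fold-change hit calling in four phenotype classes; computes exact-test
    overlap enrichment between hit lists and annotation gene sets; scores
    synthetic genetic array suppressor screens from colony sizes; and
    simulates complete screens with known ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
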