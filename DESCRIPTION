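Package: platetx
Title: Plate-Based High-Throughput Transcriptomics Screening Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: End-to-end analysis of plate-based high-throughput
    transcriptomics (HTTr) screens: sparse count-matrix and plate-metadata
    ingestion with validation, quality control with relative log expression
    (RLE) summaries and an average coefficient-of-variation score,
    library-size, trimmed-mean-of-M-values (TMM/TMMwsp) and median-of-ratios
    normalisation, zero-inflated negative binomial observation weights,
    differential expression under five statistical engines with a common
    result contract, multi-treatment screen summaries, pathway
    over-representation and preranked enrichment with permutation NES,
    four-parameter logistic dose-response fitting with EC50 extraction, a
    resampling benchmark harness (filter sweeps, vehicle-split false-positive
    estimation, replicate subsampling, control-count sweeps), and a
    ground-truth plate simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    DESeq2,
    edgeR,
    jsonlite,
    limma,
    Matrix,
    methods,
    minpack.lm,
    optparse,
    parallel,
    stats,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
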