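Package: methylDMR
Title: Differential Methylation, Expression and Small-RNA Analysis for
    Plant Silencing Studies
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse whole-genome bisulfite, RNA-seq and
    small-RNA sequencing data from plant gene-silencing experiments.
    Implements a differentially methylated region (DMR) caller based on
    Savitzky-Golay smoothing of per-cytosine read counts, per-cytosine
    and per-region Fisher's exact tests, context-specific merging (CG,
    CHG, CHH) and Benjamini-Hochberg correction; RPKM-based differential
    expression with Fisher's exact test and replicate intersection;
    compartment-enrichment statistics; methylation and siRNA
    metaprofiles; and a seeded synthetic-data generator producing
    methylomes, expression counts and small-RNA libraries with ground
    truth for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    signal,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
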