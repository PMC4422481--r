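Package: mesoscape
Title: Somatic Copy-Number and Mutation Landscape Analysis for Paired
    Tumor-Normal Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of the somatic landscape of a small tumor
    cohort from SNP-array and paired tumor-normal sequencing evidence.
    Provides exact penalized least-squares segmentation of LogR/BAF probe
    profiles with gain/loss and loss-of-heterozygosity calling, cytoband-
    and gene-level recurrence scoring across samples, a staged Fisher-exact
    tumor-normal variant classifier with a VarScan-style false-positive
    filter cascade, and integration of copy-number and mutation evidence
    into a per-sample gene-alteration status table with a cohort summary.
    A fully parameterised synthetic-data generator with recorded truth
    (tumor purity, clonal and subclonal deletions, germline and somatic
    variants, sequencing noise) makes every stage testable without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
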