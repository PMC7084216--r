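Package: moRquant
Title: Detection and Quantification of miRNAs, moRNAs and Their Isoforms
    from Small RNA-Seq Data
Version: 0.1.0
Authors@R:
    person("moRquant", "Developers", email = "morquant@example.org",
           role = c("aut", "cre"))
Description: Detects and quantifies mature microRNAs (miRNAs), their
    complementary (star) sequences, microRNA-offset RNAs (moRNAs), hairpin
    loop sequences and their sequence isoforms (isomiRs/isomoRs) from
    Illumina small RNA-seq reads, given a reference genome and a
    miRBase-style precursor/mature annotation. Reads are adapter-trimmed,
    quality filtered and collapsed into counted sequence tags; tags are
    exactly matched to the genome with a multi-mapping discard rule,
    aligned to extended hairpin precursors (precursor plus 30 nt flanks)
    allowing up to two mismatches, clustered into alignment blocks, and
    assigned to up to five small RNA products per precursor. A seeded
    simulator with planted truth provides the test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    Rcpp,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
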