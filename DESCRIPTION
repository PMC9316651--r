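Package: sclpCNV
Title: Single-Cell Low-Pass Copy-Number Profiling and Quality Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed copy-number analysis for single-cell low-pass whole-genome
    sequencing, aimed at circulating tumor cells amplified with PCR-based whole
    genome amplification. Bins mapped reads into fixed megabase windows over an
    hg19-like genome model, normalizes to copy number at a fixed ploidy, segments
    profiles by penalized least squares, and calls integer, arm-level and
    gene-level copy-number states. Implements the single-cell QC battery used to
    gate such libraries: genome integrity index (GII) from four diagnostic PCR
    bands, a mapped-read minimum, derivative log ratio spread (DLRS) on a seeded
    200,000-read subsample, and the R50 library-complexity metric over
    amplification fragments. A synthetic-data module generates
    restriction-fragment libraries with lognormal amplification bias, fragment
    dropout and unmapped contamination over ground-truth copy-number profiles, so
    the whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
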