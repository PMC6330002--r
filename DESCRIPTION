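Package: qualcrunch
Title: Reference-Free Lossy Compression of Alignment Base Quality Values
Version: 0.9.0
Authors@R:
    person("Quality", "Crunch Developers", email = "qualcrunch@example.org",
           role = c("aut", "cre"))
Description: Lossy, reference-free compression of per-base quality values in
    coordinate-sorted SAM/BAM alignment files.  A fast, deliberately
    pessimistic diploid consensus caller (pileup-column based, with deletion
    treated as a fifth base) decides where qualities can be replaced by
    constants, a set of unreliability heuristics (concordant soft clipping,
    excessive depth, low mapping quality, excess alleles, low-confidence
    calls, short tandem repeats) decides where they must be kept verbatim,
    and an optional P-block pass smooths the kept values.  Includes a
    truth-tracked read simulator so every stage is testable without external
    data, plus a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    IRanges,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
SystemRequirements: samtools (optional; only for BAM input/output)
Config/testthat/edition: 3
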