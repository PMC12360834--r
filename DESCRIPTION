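Package: bishash
Title: Bisulfite Read Alignment via Multi-Metric MinHash Sketching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns directional bisulfite sequencing reads to a reference
    genome using multi-metric MinHash (M3Hash) sketches. Overlapping
    reference segments are sketched under two k-mer equivalence metrics
    (exact identity and C/T or G/A letter collapse), candidate segments are
    selected by sketch-value voting, and exact positions are resolved with a
    bisulfite-asymmetric local alignment in which genomic-C versus read-T
    (or genomic-G versus read-A) pairs score as matches. Includes a
    methylation-aware bisulfite read simulator, an alignment evaluator with
    a 1 bp positional tolerance and false discovery rate, and a command-line
    interface covering the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
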