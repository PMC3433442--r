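Package: hairpinforge
Title: Small RNA Profiling, Hairpin-Based miRNA Discovery and Expression
    Analysis for Plant Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for plant small RNA sequencing analysis:
    adapter trimming and read collapsing into unique tags, size and 5'-base
    population profiling, conserved microRNA identification by
    mismatch-tolerant mapping against known precursors, novel microRNA
    discovery by hairpin excision and secondary-structure filtering (free
    energy, minimal folding free energy index, duplex asymmetry and the
    standard plant annotation criteria), penalty-score target prediction,
    2^-ddCq expression and stress-response analysis, and strand-resolved
    organelle coverage profiling. Ships a deterministic synthetic-data
    generator that plants hairpin precursors, decoy loci and Cq effects so
    every pipeline stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
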