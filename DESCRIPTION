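Package: magladder
Title: Coverage-Based Metagenome Binning with Affinity Propagation and
    Marker-Gene Quality Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers draft metagenome-assembled genomes (MAGs) from
    multi-sample assemblies by clustering contigs on per-sample read
    coverage profiles (reads/bp) with affinity propagation, assessing bins
    against a universal single-copy marker set (completeness,
    contamination, strain heterogeneity, cumulative redundancy), and
    refining contaminated bins through a multi-round preference ladder.
    Includes length-normalized relative abundance of recovered genomes, a
    synthetic multi-sample community generator with known truth labels for
    validation, and truth-based evaluation metrics (adjusted Rand index,
    per-genome recovery).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    mclust,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    withr
Config/testthat/edition: 3
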