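Package: numtscan
Title: Detection and Phylogenetics of Nuclear Mitochondrial Insertions (NUMTs)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens genome assemblies for nuclear copies of the
    mitochondrial cox1 gene (NUMTs). Provides a self-contained
    seed-and-extend local aligner with an affine-gap Smith-Waterman
    verification oracle, ingestion of blastn tabular (outfmt 6) hit
    files, a three-stage exclusion filter (minimum alignment length,
    near-complete scaffold span, scaffold-edge placement), merging of
    surviving hits into insertion sites, sequence extraction, and a
    reference-anchored multiple alignment with Jukes-Cantor distances,
    neighbour-joining trees and per-species monophyly tests. A
    synthetic-genome simulator plants ground-truthed cox1 fragments at
    controlled divergence so every pipeline stage can be validated
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
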