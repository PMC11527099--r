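Package: mafconserve
Title: Motif Detection and Conservation Scoring in Multiple Alignment
    Format Files
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects motif instances (literal k-mers, regular expressions,
    or JASPAR position weight matrices) in a chosen genome row of each
    block of a Multiple Alignment Format (MAF) file, and quantifies the
    conservation of every instance across the aligned genomes through
    gap-aware binary similarity vectors and conservation percentages.
    K-mer sets are located with an Aho-Corasick multi-pattern automaton,
    PWM score thresholds are calibrated by Monte-Carlo sampling from a
    background nucleotide model at a target p-value, and reverse-strand
    search is supported for all three motif classes. Results are written
    as JSON and CSV reports; a synthetic MAF generator with planted
    motifs and known ground truth supports testing end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    parallel,
    jsonlite,
    Rcpp,
    Biostrings,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: MotifDiscovery, SequenceMatching, Alignment, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
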