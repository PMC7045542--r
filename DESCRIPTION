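Package: fragte
Title: Completeness-Independent Sieving of Closely Related Prokaryotic Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Alignment-free pre-selection ("sieving") of closely related
    prokaryotic genome pairs ahead of whole-genome comparisons such as average
    nucleotide identity. Implements the FRAGTE algorithm, which fragments each
    genome with a sliding window, selects a representative fragment by maximal
    accumulated tetranucleotide similarity, and decides pairs with empirically
    calibrated length-specific cutoffs plus a genome-specific cutoff, making
    the decision robust to genome incompleteness. Also provides the
    whole-genome tetranucleotide z-score baseline (TETRA), the cutoff
    calibration procedure, a seeded synthetic species/strain benchmark
    generator with completeness and MAG-like degradation, and
    sensitivity/specificity benchmarking utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
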