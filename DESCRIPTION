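Package: rdnarray
Title: Copy Number and Intragenomic Variation in Ribosomal RNA Repeat Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of ribosomal RNA (rDNA) tandem-repeat arrays from
    whole-genome shotgun data. Estimates repeat copy number from the ratio of
    repeat coverage to genome-wide sequencing depth, builds majority-rule
    consensus repeats from read pileups, calls intragenomic polymorphisms with
    a coverage-scaled error-filtering threshold, classifies interspecific
    divergence into transitions, transversions and complex events, computes
    per-generation copy-number expansion rates for mutation-accumulation
    lines, and applies the Vg/Vm ratio test for purifying selection. A
    synthetic shotgun-data generator with known truth supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
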