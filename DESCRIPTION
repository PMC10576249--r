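Package: asvscreen
Title: Screening DNA Metabarcoding ASV Tables for Non-Local Species and
    Contamination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quality-control pipeline for amplicon sequence variant (ASV)
    tables from DNA metabarcoding studies. Assigns taxonomic identities
    against a local COI barcode reference library using BOLD-style decision
    rules (identity and coverage thresholds, tie resolution with preference
    for locally occurring species), applies relative read abundance (RRA)
    filtering with renormalization, flags observations of species whose known
    ranges lie far from the study area as putative false positives, analyses
    their occurrence patterns over field-collection and lab-processing
    orderings, and traces candidate contamination sources by sequence
    matching, p-distance neighbor-joining trees and homopolymer
    sequencing-error detection. Includes a seeded synthetic-data generator
    that emulates contamination scenarios (lab point-source, field
    environmental, background carryover) with ground-truth labels for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ape,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
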