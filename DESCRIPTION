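Package: gebvacc
Title: Deterministic Prediction of Genomic EBV Accuracy in Selection Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic prediction of the accuracy of genomic estimated
    breeding values (GEBV) for selection candidates in closed breeding
    populations. Partitions GEBV information into a pedigree component and a
    genomic-deviation component using Fisher-information and selection-index
    algebra, estimates the effective number of chromosome segments (Me) from
    observed accuracies, from relationship-matrix variances, or from
    theoretical population-genetic formulas, and models the erosion of
    genomic information across generations through segment recombination.
    Includes pedigree (A) and VanRaden genomic (G) relationship matrices, a
    dense single-trait BLUP/GBLUP solver, empirical accuracy estimation by
    efficient leave-one-out cross-validation and the LR part-whole method,
    and a forward-in-time stochastic breeding-program simulator used to
    validate the deterministic predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
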