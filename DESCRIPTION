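Package: mitorho
Title: Mitogenome Variant Calling, Haplogroup Classification and
    Rho-Statistic TMRCA Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for whole-mitogenome phylogenetics in the rCRS coordinate
    frame: parsing and formatting of mtDNA variant nomenclature, banded-
    alignment variant calling against a packaged reference, haplogroup
    classification against a PhyloTree-style definition tree with weighted
    Kulczynski scoring, maximum-parsimony haplotype trees within clades,
    and rho-statistic TMRCA estimation with Saillard-type standard errors
    under explicitly calibrated molecular clocks. Includes a coalescent-style
    cohort simulator with known genealogies so every pipeline stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
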