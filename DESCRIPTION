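Package: dfspectrum
Title: The D Frequency Spectrum for Detecting and Characterising Introgression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the D frequency spectrum (DFS), a stratification of the
    ABBA-BABA D-statistic by derived-allele-frequency bins, from genotype data
    (VCF plus a population map) or from a polarized joint site frequency
    spectrum. Includes exact hypergeometric SFS projection, outgroup-based
    polarization, a Monte Carlo structured-coalescent simulator of unlinked
    sites with named demographic scenario presets (timing of gene flow,
    bottlenecks, bidirectional flow, ancestral structure), bootstrap standard
    errors for the stratified statistics, ggplot2 visualisation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
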