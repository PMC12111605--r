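Package: sweepscan
Title: Selection-Signature Scans from Phased Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects signatures of selection in diploid populations from
    phased genotypes: within-population integrated haplotype scores (iHS)
    and between-population XP-EHH and Rsb statistics built on extended
    haplotype homozygosity (EHH/EHHS), PLINK-style runs-of-homozygosity
    calling with length-class spectra, ROH-based inbreeding (F_ROH) and
    ROH-island tracks, LD-based effective-population-size trajectories,
    variant quality control (call rate, MAF, exact Hardy-Weinberg test),
    genomic relationship matrices with PCA, significance calling and
    candidate-region merging with gene annotation, and a two-population
    forward Wright-Fisher simulator with recombination and selective
    sweeps for validation. Results are tibbles that pipe into dplyr and
    ggplot2.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    vcfR,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    cluster,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
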