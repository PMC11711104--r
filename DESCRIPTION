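Package: sebpanel
Title: Diagnostic SNP Panels for Redfish (Sebastes) Species Identification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovers diagnostic SNP panels that separate species and
    cryptic species from genotype and read-depth data, computes per-locus
    diversity statistics (observed and expected heterozygosity, inbreeding
    coefficient, minor allele frequency, exact Hardy-Weinberg tests),
    assigns individuals to species from multilocus genotype rules, and
    quantifies between-group divergence with Cavalli-Sforza-Edwards chord
    distances, neighbor-joining trees with locus-bootstrap support, and
    allele-dosage PCA. A synthetic cohort generator with planted fixed
    differences, overdispersed read depths, missing calls and genotyping
    errors makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
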