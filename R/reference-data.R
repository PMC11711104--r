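#' Published per-locus summary for the 47-SNP redfish panel
#'
#' The reference per-locus statistics reported for the 47 biallelic SNPs of
#' the Northeast-Atlantic *Sebastes* identification panel, genotyped in 191
#' fish pooled across species: typed count `N`, allele count `Na`, observed
#' (`Ho`) and expected (`He`) heterozygosity, inbreeding coefficient `F`,
#' HWE significance stars, minor allele frequency `MAF` and the two
#' alleles. Because the cohort pools reproductively isolated species, every
#' locus shows a Wahlund-style heterozygote deficiency (all `F` > 0,
#' deviation from HWE).
#'
#' @return A 47-row tibble.
#' @export
sebastes_panel_summary <- function() {
  path <- system.file("extdata", "sebastes_panel_summary.csv",
                      package = "sebpanel", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    Locus = "c", N = "i", Na = "i", Ho = "d", He = "d",
                    F = "d", Signif = "c", MAF = "d", A1 = "c", A2 = "c"))
}
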