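# Shared fixture builders; everything is generated in code at test time.

# calls tibble from a wide genotype spec: list(indiv = c(loc1 = "CC", ...))
calls_from_wide <- function(spec, depth = NULL) {
  purrr::imap_dfr(spec, function(gts, ind) {
    tibble::tibble(
      indiv = ind, locus = names(gts),
      a1 = ifelse(gts == "NN", NA_character_, substr(gts, 1, 1)),
      a2 = ifelse(gts == "NN", NA_character_, substr(gts, 2, 2)),
      depth = if (is.null(depth)) NA_integer_ else depth)
  })
}

# a minimal clean two-group cohort fixed for alternative alleles at `n_loci`
fixed_two_group_cohort <- function(n_per_group = 5, n_loci = 3,
                                   depth = 30L) {
  loci <- sprintf("L%02d", seq_len(n_loci))
  calls <- purrr::map_dfr(seq_len(2 * n_per_group), function(i) {
    grp_a <- i <= n_per_group
    al <- if (grp_a) "A" else "G"
    tibble::tibble(indiv = sprintf("ind%02d", i), locus = loci,
                   a1 = al, a2 = al, depth = depth)
  })
  loci_tbl <- tibble::tibble(
    locus = loci, contig = paste0("ctg", seq_len(n_loci)),
    pos = 100L * seq_len(n_loci), ref = "A", alt = "G", qual = 900)
  groups <- tibble::tibble(
    indiv = sprintf("ind%02d", seq_len(2 * n_per_group)),
    group = rep(c("grpA", "grpB"), each = n_per_group))
  ch <- new_cohort(calls, loci_tbl, groups)
  attr(ch, "contig_lengths") <- setNames(rep(30000, n_loci),
                                         loci_tbl$contig)
  ch
}

# toy 3-sample VCF exercising GT:DP, missing, phased and multi-allelic calls
write_toy_vcf <- function(path, add_indel = FALSE) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=ctg1,length=30000>",
    "##contig=<ID=ctg2,length=15000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    paste(c("ctg1", "100", "L1", "C", "T", "900", "PASS", ".",
            "GT:DP", "0/0:30", "0/1:25", "./.:10"), collapse = "\t"),
    paste(c("ctg2", "200", "L2", "A", "G,T", "750.5", "PASS", ".",
            "GT:DP", "1/2:40", "0|0:22", "./1:33"), collapse = "\t"))
  if (add_indel) {
    lines <- c(lines, paste(c("ctg1", "150", "L3", "C", "CTT", "600",
                              "PASS", ".", "GT:DP", "0/0:9", "0/1:9",
                              "1/1:9"), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

# exact HWE oracle: direct factorial arithmetic over heterozygote counts,
# independent of the lgamma-based implementation
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  hs <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  prob <- vapply(hs, function(h) {
    factorial(n) / (factorial((nA - h) / 2) * factorial(h) *
                      factorial((na - h) / 2)) *
      2^h * factorial(nA) * factorial(na) / factorial(2 * n)
  }, numeric(1))
  prob <- prob / sum(prob)
  p_obs <- prob[hs == n_Aa]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-9)]))
}

# cohort where every locus carries a distinct fixed allele per group:
# every pair of groups is maximally separated at every locus
fully_separated_cohort <- function(n_loci = 30, n_per_group = 10) {
  gnames <- c("g1", "g2", "g3", "g4")
  al <- c(g1 = "A", g2 = "C", g3 = "G", g4 = "T")
  calls <- purrr::map_dfr(gnames, function(g) {
    purrr::map_dfr(seq_len(n_per_group), function(i) {
      tibble::tibble(indiv = sprintf("%s_%02d", g, i),
                     locus = sprintf("L%02d", seq_len(n_loci)),
                     a1 = al[[g]], a2 = al[[g]])
    })
  })
  groups <- calls |> dplyr::distinct(indiv) |>
    dplyr::mutate(group = sub("_.*", "", indiv))
  new_cohort(calls, groups = groups)
}
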