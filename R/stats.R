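#' Per-locus allele frequencies
#'
#' Frequencies over the `2N` allele draws from typed calls, per locus.
#'
#' @param x A `seb_cohort` or calls tibble (columns `locus`, `a1`, `a2`).
#' @return Tibble: `locus`, `allele`, `count`, `freq`; frequencies sum to 1
#'   within each locus.
#' @export
allele_freqs <- function(x) {
  calls <- cohort_calls(x)
  typed <- calls[!is.na(calls$a1), , drop = FALSE]
  if (nrow(typed) == 0) abort("all calls are MISSING")
  all_missing <- setdiff(unique(calls$locus), unique(typed$locus))
  if (length(all_missing)) {
    abort(paste0("locus with no typed calls: ",
                 paste(head(all_missing, 5), collapse = ", ")))
  }
  long <- tibble::tibble(
    locus = rep(typed$locus, 2),
    allele = c(typed$a1, typed$a2))
  long |>
    dplyr::count(.data$locus, .data$allele, name = "count") |>
    dplyr::group_by(.data$locus) |>
    dplyr::mutate(freq = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$locus, .data$allele)
}

#' Gene diversity (expected heterozygosity) from allele frequencies
#'
#' Plain `1 - sum(p^2)` form (GenAlEx convention, no small-sample
#' correction); the unbiased variant `2N/(2N-1) * (1 - sum p^2)` is
#' available with `unbiased = TRUE`.
#'
#' @param p Numeric vector of allele frequencies (sums to 1).
#' @param n Number of typed individuals (needed only when `unbiased`).
#' @param unbiased Apply the `2N/(2N-1)` correction.
#' @return Expected heterozygosity in `[0, 1]`.
#' @export
gene_diversity <- function(p, n = NULL, unbiased = FALSE) {
  stopifnot(abs(sum(p) - 1) < 1e-8)
  he <- 1 - sum(p^2)
  if (unbiased) {
    stopifnot(!is.null(n), n >= 1)
    he <- he * 2 * n / (2 * n - 1)
  }
  he
}

#' Exact Hardy-Weinberg test for a biallelic locus
#'
#' Conditional on the observed allele counts, enumerates every possible
#' heterozygote count (same parity as the minor-allele count) and sums the
#' probabilities of all configurations whose conditional probability is at
#' most that of the observed one (two-sided exact test).
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total >= 1).
#' @return Exact p-value in `(0, 1]`; 1 for monomorphic input.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) abort("total genotype count must be >= 1")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  n_minor <- min(nA, na)
  h <- seq(n_minor %% 2, n_minor, by = 2)
  logp <- lgamma(n + 1) - lgamma((nA - h) / 2 + 1) - lgamma(h + 1) -
    lgamma((na - h) / 2 + 1) + h * log(2) +
    lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[h == n_Aa]
  min(1, sum(p[p <= p_obs * (1 + 1e-10)]))
}

#' Summarise one locus: N, Na, Ho, He, F, MAF, alleles, HWE p-value
#'
#' `Ho` = heterozygote fraction among typed individuals; `He` = gene
#' diversity `1 - sum(p^2)`; `F` = `(He - Ho)/He`, `NA` (undefined) when
#' `He = 0`; `MAF` = smallest allele frequency for biallelic loci, 0 when
#' monomorphic, `NA` for >2 alleles. The exact HWE p-value is computed for
#' biallelic loci (1 for monomorphic, `NA` otherwise).
#'
#' @param x A `seb_cohort` or calls tibble; with `locus_id`, a single locus
#'   is summarised, otherwise all loci.
#' @param locus_id Optional single locus label.
#' @param unbiased Use the small-sample-corrected He.
#' @return Tibble with columns `locus`, `N`, `Na`, `Ho`, `He`, `F`, `MAF`,
#'   `hwe_p`, `A1`, `A2`.
#' @export
locus_summary <- function(x, locus_id = NULL, unbiased = FALSE) {
  calls <- cohort_calls(x)
  if (!is.null(locus_id)) {
    calls <- calls[calls$locus %in% locus_id, , drop = FALSE]
    if (nrow(calls) == 0) abort(paste0("no such locus: ", locus_id))
  }
  locus_order <- unique(calls$locus)
  freqs <- allele_freqs(calls)
  one <- function(l) {
    cc <- calls[calls$locus == l & !is.na(calls$a1), , drop = FALSE]
    fr <- freqs[freqs$locus == l, , drop = FALSE]
    n <- nrow(cc)
    na <- nrow(fr)
    ho <- mean(cc$a1 != cc$a2)
    he <- gene_diversity(fr$freq, n = n, unbiased = unbiased)
    f <- if (he > 0) (he - ho) / he else NA_real_
    maf <- if (na == 1) 0 else if (na == 2) min(fr$freq) else NA_real_
    hwe <- if (na > 2) {
      NA_real_
    } else if (na == 1) {
      1
    } else {
      als <- fr$allele
      n_hom1 <- sum(cc$a1 == als[1] & cc$a2 == als[1])
      n_het <- sum(cc$a1 != cc$a2)
      n_hom2 <- sum(cc$a1 == als[2] & cc$a2 == als[2])
      hwe_exact_test(n_hom1, n_het, n_hom2)
    }
    tibble::tibble(
      locus = l, N = n, Na = na, Ho = ho, He = he, F = f, MAF = maf,
      hwe_p = hwe,
      A1 = fr$allele[1],
      A2 = if (na >= 2) fr$allele[2] else NA_character_)
  }
  purrr::map_dfr(locus_order, one)
}

#' Significance stars for HWE p-values
#' @param p Numeric p-values.
#' @return `"***"` for p < 0.001, `"**"` for p < 0.01, `"ns"` otherwise,
#'   `""` for `NA`.
#' @export
signif_stars <- function(p) {
  dplyr::case_when(is.na(p) ~ "", p < 0.001 ~ "***", p < 0.01 ~ "**",
                   TRUE ~ "ns")
}

#' Per-locus summary table in panel-report layout
#'
#' One row per locus in matrix order with columns `Locus`, `N`, `Na`,
#' `Ho`, `He`, `F`, `Signif`, `MAF`, `A1`, `A2`. With `groups`, the table
#' is computed within each group and stacked with a leading `Group`
#' column; without, the pooled cohort is summarised (where reproductively
#' isolated groups are pooled, a Wahlund-style heterozygote deficiency is
#' the expected signature).
#'
#' @param x A `seb_cohort` or calls tibble.
#' @param groups Optional `indiv`/`group` tibble (`NULL` = pooled; pass
#'   `cohort_groups(x)` for per-group tables).
#' @param path Optional CSV output path; display columns are rounded to 3
#'   decimals in the file only.
#' @return The summary tibble (full precision).
#' @export
summary_table <- function(x, groups = NULL, path = NULL) {
  calls <- cohort_calls(x)
  make <- function(cc) {
    locus_summary(cc) |>
      dplyr::mutate(Signif = signif_stars(.data$hwe_p)) |>
      dplyr::select(Locus = "locus", "N", "Na", "Ho", "He", "F", "Signif",
                    "MAF", "A1", "A2", "hwe_p")
  }
  out <- if (is.null(groups)) {
    make(calls)
  } else {
    purrr::map_dfr(unique(groups$group), function(g) {
      cc <- calls |>
        dplyr::semi_join(groups[groups$group == g, , drop = FALSE],
                         by = "indiv")
      dplyr::mutate(make(cc), Group = g, .before = 1)
    })
  }
  if (!is.null(path)) {
    disp <- out |>
      dplyr::mutate(dplyr::across(dplyr::all_of(c("Ho", "He", "F", "MAF")),
                                  ~ round(.x, 3))) |>
      dplyr::select(-"hwe_p")
    readr::write_csv(disp, path)
  }
  out
}

#' G statistic of a two-way contingency table
#' @param tab A matrix of counts.
#' @return The likelihood-ratio statistic `2 * sum O log(O/E)`.
#' @keywords internal
g_statistic <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  o <- tab[tab > 0]
  2 * sum(o * log(o / e[tab > 0]))
}

#' Genotypic linkage-disequilibrium permutation test
#'
#' Tests association between the genotypes at two loci with the G
#' statistic on the genotype x genotype contingency table of individuals
#' typed at both, against a null built by permuting one locus's individual
#' assignment. `p = (1 + #{G* >= G_obs}) / (n_perm + 1)`.
#'
#' @param x A `seb_cohort` or calls tibble containing both loci.
#' @param locus_a,locus_b Locus labels.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for reproducibility.
#' @return A tibble with `g_obs`, `p_value`, `n_used`.
#' @export
ld_permutation_test <- function(x, locus_a, locus_b, n_perm = 999,
                                seed = 1L) {
  stopifnot(n_perm >= 100)
  calls <- cohort_calls(x)
  gt_of <- function(l) {
    cc <- calls[calls$locus == l, , drop = FALSE]
    setNames(ifelse(is.na(cc$a1), NA_character_,
                    paste0(cc$a1, cc$a2)), cc$indiv)
  }
  ga <- gt_of(locus_a)
  gb <- gt_of(locus_b)
  common <- intersect(names(ga)[!is.na(ga)], names(gb)[!is.na(gb)])
  ga <- ga[common]
  gb <- gb[common]
  if (dplyr::n_distinct(ga) < 2 || dplyr::n_distinct(gb) < 2) {
    return(tibble::tibble(g_obs = NA_real_, p_value = 1,
                          n_used = length(common)))
  }
  g_obs <- g_statistic(table(ga, gb))
  withr::local_seed(seed)
  g_perm <- vapply(seq_len(n_perm), function(i)
    g_statistic(table(ga, sample(gb))), numeric(1))
  p <- (1 + sum(g_perm >= g_obs - 1e-12)) / (n_perm + 1)
  tibble::tibble(g_obs = g_obs, p_value = p, n_used = length(common))
}
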