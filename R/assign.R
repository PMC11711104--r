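#' Built-in three-SNP redfish species rules
#'
#' The published multilocus signatures over the SEB29 / SEB39 / SEB25
#' TaqMan loci: SEB29 separates *S. viviparus*, SEB39 separates
#' *S. mentella*, and SEB25 splits the two cryptic *S. norvegicus* types.
#'
#' @return A rule tibble: `species`, `locus`, `genotype` (sorted
#'   two-character call).
#' @export
#' @examples
#' sebastes_rules()
sebastes_rules <- function() {
  path <- system.file("extdata", "sebastes_rules.json",
                      package = "sebpanel", mustWork = TRUE)
  read_rules(path)
}

#' Read a species rule table from JSON
#'
#' Schema: `{"species": {"locus": "CC", ...}, ...}`. Rule order in the
#' file is preserved but assignment is invariant to it.
#'
#' @param path Path to a rules JSON file.
#' @return A rule tibble (`species`, `locus`, `genotype`).
#' @export
read_rules <- function(path) {
  raw <- jsonlite::read_json(path)
  if (!length(raw)) abort("empty ruleset")
  rules <- purrr::imap_dfr(raw, function(loci, sp)
    tibble::tibble(species = sp, locus = names(loci),
                   genotype = unlist(loci)))
  norm <- normalize_genotype(substr(rules$genotype, 1, 1),
                             substr(rules$genotype, 2, 2))
  rules$genotype <- paste0(norm$a1, norm$a2)
  sig <- rules |>
    dplyr::arrange(.data$locus) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(sig = paste(.data$locus, .data$genotype,
                                 collapse = ";"), .groups = "drop")
  if (anyDuplicated(sig$sig)) abort("two rules share an identical signature")
  rules
}

#' Assign individuals to species by diagnostic genotype rules
#'
#' Each species rule is scored by exact genotype matches over non-missing
#' rule loci. An individual is assigned to the unique best-matching rule
#' provided its conflicts are at most `max_conflicts` and its missing rule
#' loci at most `max_missing`; ties or exceeded thresholds yield
#' `UNASSIGNED` with diagnostics. Heterozygous observations at a rule
#' locus count as conflicts, never half-matches, so anomalies surface.
#'
#' @param x A `seb_cohort` or calls tibble covering the rule loci.
#' @param rules A rule tibble, e.g. [sebastes_rules()].
#' @param max_conflicts Maximum mismatched rule loci tolerated (default 0).
#' @param max_missing Maximum missing rule loci tolerated (default 0).
#' @return Tibble, one row per individual: `indiv`, `species`
#'   (`"UNASSIGNED"` when no call), `method`, `n_match`, `n_conflict`,
#'   `n_missing`, and list-columns `conflicts` (tibbles locus/observed/
#'   expected) and `missing_loci`.
#' @export
assign_by_rules <- function(x, rules, max_conflicts = 0, max_missing = 0) {
  if (is.null(rules) || nrow(rules) == 0) abort("empty ruleset")
  calls <- cohort_calls(x)
  rule_loci <- unique(rules$locus)
  species <- unique(rules$species)
  obs <- calls[calls$locus %in% rule_loci, , drop = FALSE] |>
    dplyr::mutate(gt = ifelse(is.na(.data$a1), NA_character_,
                              paste0(.data$a1, .data$a2)))

  one <- function(ind) {
    g <- setNames(rep(NA_character_, length(rule_loci)), rule_loci)
    oi <- obs[obs$indiv == ind, , drop = FALSE]
    g[oi$locus] <- oi$gt
    score <- purrr::map_dfr(species, function(sp) {
      r <- rules[rules$species == sp, , drop = FALSE]
      expct <- setNames(r$genotype, r$locus)
      got <- g[r$locus]
      miss <- is.na(got)
      match_ <- !miss & got == expct
      confl <- !miss & got != expct
      tibble::tibble(
        species = sp, n_match = sum(match_), n_conflict = sum(confl),
        n_missing = sum(miss),
        conflicts = list(tibble::tibble(
          locus = r$locus[confl], observed = unname(got[confl]),
          expected = unname(expct[confl]))),
        missing_loci = list(r$locus[miss]))
    })
    best <- max(score$n_match)
    top <- score[score$n_match == best, , drop = FALSE]
    ok <- nrow(top) == 1 && best > 0 &&
      top$n_conflict <= max_conflicts && top$n_missing <= max_missing
    if (ok) {
      dplyr::mutate(top, indiv = ind, method = "rules", .before = 1)
    } else {
      tibble::tibble(
        indiv = ind, method = "rules", species = "UNASSIGNED",
        n_match = best,
        n_conflict = if (nrow(top) == 1) top$n_conflict else NA_integer_,
        n_missing = if (nrow(top) == 1) top$n_missing else NA_integer_,
        conflicts = if (nrow(top) == 1) top$conflicts else list(NULL),
        missing_loci = if (nrow(top) == 1) top$missing_loci else list(NULL))
    }
  }
  purrr::map_dfr(unique(calls$indiv), one) |>
    dplyr::select("indiv", "species", "method", "n_match", "n_conflict",
                  "n_missing", "conflicts", "missing_loci")
}

#' Per-group allele frequency table
#'
#' Frequencies within each labelled group at every locus, with the typed
#' individual count; feeds chord distances, likelihood assignment and the
#' locus bootstrap.
#'
#' @param x A `seb_cohort` with groups (or a calls tibble plus `groups`).
#' @param groups Optional `indiv`/`group` tibble.
#' @return Tibble: `group`, `locus`, `allele`, `count`, `freq`, `n_typed`.
#' @export
group_allele_freqs <- function(x, groups = NULL) {
  calls <- cohort_calls(x)
  groups <- groups %||% cohort_groups(x)
  if (is.null(groups)) abort("group labels are required")
  purrr::map_dfr(unique(groups$group), function(g) {
    cc <- calls |>
      dplyr::semi_join(groups[groups$group == g, , drop = FALSE],
                       by = "indiv")
    cc <- cc[!is.na(cc$a1), , drop = FALSE]
    if (nrow(cc) == 0) return(tibble::tibble())
    n_typed <- cc |>
      dplyr::count(.data$locus, name = "n_typed")
    allele_freqs(cc) |>
      dplyr::left_join(n_typed, by = "locus") |>
      dplyr::mutate(group = g, .before = 1)
  })
}

#' Assign individuals by multilocus Hardy-Weinberg likelihood
#'
#' For each group, the log-likelihood of an individual is the sum over its
#' typed loci of the log Hardy-Weinberg genotype probability under that
#' group's allele frequencies. Frequencies are floored at
#' `eps = 1/(2 N_typed + 1)` per group and locus so unseen alleles stay
#' finite. The individual is assigned to the arg-max group when its
#' natural-log margin over the runner-up is at least `min_margin`,
#' otherwise `UNASSIGNED`.
#'
#' @param x A `seb_cohort` or calls tibble for the individuals to assign.
#' @param freqs A [group_allele_freqs()] table from a reference cohort.
#' @param min_margin Minimum log-likelihood margin (natural-log units).
#' @return Tibble: `indiv`, `species`, `method`, `loglik`, `margin`,
#'   `n_loci_used`.
#' @export
assign_by_likelihood <- function(x, freqs, min_margin = 2) {
  calls <- cohort_calls(x)
  gnames <- unique(freqs$group)
  if (!length(gnames)) abort("empty frequency table")
  # lookup: group -> locus -> named freq vector + eps
  ftab <- freqs |>
    dplyr::group_by(.data$group, .data$locus) |>
    dplyr::summarise(f = list(setNames(.data$freq, .data$allele)),
                     eps = 1 / (2 * .data$n_typed[1] + 1),
                     .groups = "drop")

  one <- function(ind) {
    cc <- calls[calls$indiv == ind & !is.na(calls$a1), , drop = FALSE]
    if (nrow(cc) == 0) {
      return(tibble::tibble(indiv = ind, species = "UNASSIGNED",
                            method = "likelihood", loglik = NA_real_,
                            margin = NA_real_, n_loci_used = 0L))
    }
    ll <- vapply(gnames, function(g) {
      ft <- ftab[ftab$group == g & ftab$locus %in% cc$locus, , drop = FALSE]
      if (nrow(ft) == 0) return(NA_real_)
      rows <- match(ft$locus, cc$locus)
      sum(vapply(seq_len(nrow(ft)), function(i) {
        f <- ft$f[[i]]
        eps <- ft$eps[i]
        a1 <- cc$a1[rows[i]]
        a2 <- cc$a2[rows[i]]
        p1 <- max(f[a1], eps, na.rm = TRUE)
        p2 <- max(f[a2], eps, na.rm = TRUE)
        if (a1 == a2) 2 * log(p1) else log(2) + log(p1) + log(p2)
      }, numeric(1)))
    }, numeric(1))
    ll <- ll[!is.na(ll)]
    if (!length(ll)) {
      return(tibble::tibble(indiv = ind, species = "UNASSIGNED",
                            method = "likelihood", loglik = NA_real_,
                            margin = NA_real_, n_loci_used = nrow(cc)))
    }
    ord <- order(ll, decreasing = TRUE)
    margin <- if (length(ll) > 1) unname(ll[ord[1]] - ll[ord[2]]) else Inf
    tibble::tibble(
      indiv = ind,
      species = if (margin >= min_margin) names(ll)[ord[1]] else "UNASSIGNED",
      method = "likelihood", loglik = unname(ll[ord[1]]),
      margin = margin, n_loci_used = nrow(cc))
  }
  purrr::map_dfr(unique(calls$indiv), one)
}
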