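#' Discovery thresholds for diagnostic SNP selection
#'
#' Defaults follow the redfish panel protocol: Phred quality strictly
#' greater than 500, mean coverage strictly greater than 20x in both groups
#' of a pair, and one SNP retained per contig strictly longer than 20 kb.
#'
#' @param min_qual Phred-scaled quality threshold (strict `>`).
#' @param min_depth Coverage threshold in x (strict `>`). With
#'   `depth_mode = "group_mean"` it applies to the mean depth over typed
#'   calls per group; with `"per_individual"` every typed call must exceed
#'   it.
#' @param min_contig_length Contig length gate in bp (strict `>`); shorter
#'   contigs are ineligible for the panel.
#' @param max_group_missing Maximum fraction of a group allowed untyped at
#'   a candidate locus (default 0: complete typing required).
#' @param depth_mode `"group_mean"` (default) or `"per_individual"`.
#' @return A `discovery_config` list.
#' @export
discovery_config <- function(min_qual = 500, min_depth = 20,
                             min_contig_length = 20000,
                             max_group_missing = 0,
                             depth_mode = c("group_mean", "per_individual")) {
  stopifnot(min_qual >= 0, min_depth >= 0, min_contig_length >= 0,
            max_group_missing >= 0, max_group_missing <= 1)
  structure(list(min_qual = min_qual, min_depth = min_depth,
                 min_contig_length = min_contig_length,
                 max_group_missing = max_group_missing,
                 depth_mode = match.arg(depth_mode)),
            class = "discovery_config")
}

#' Filter loci on Phred-scaled quality
#'
#' @param loci Tibble with at least `locus` and `qual` columns.
#' @param min_qual Threshold; loci with `qual` strictly greater are kept,
#'   in their original order.
#' @return The filtered tibble.
#' @export
filter_quality <- function(loci, min_qual = 500) {
  stopifnot(is.data.frame(loci), "qual" %in% names(loci))
  if (any(is.na(loci$qual))) abort("qual must be populated for all loci")
  loci[loci$qual > min_qual, , drop = FALSE]
}

#' Find loci reciprocally fixed between one pair of groups
#'
#' A locus is a candidate for pair (G1, G2) iff every typed individual of
#' G1 is homozygous for one allele `a`, every typed individual of G2 is
#' homozygous for a different allele `b`, the coverage criterion holds in
#' each group, and the untyped fraction per group is at most
#' `max_group_missing`.
#'
#' @param x A `seb_cohort` with group labels (or a calls tibble plus
#'   `groups`).
#' @param pair Character vector of two group names.
#' @param config A [discovery_config()].
#' @param groups Optional `indiv`/`group` tibble when `x` is a bare calls
#'   tibble.
#' @return Tibble of candidates: `locus`, `group_1`, `group_2`,
#'   `allele_1`, `allele_2`, `mean_depth_1`, `mean_depth_2`.
#' @export
find_pairwise_diagnostic <- function(x, pair, config = discovery_config(),
                                     groups = NULL) {
  calls <- cohort_calls(x)
  groups <- groups %||% cohort_groups(x)
  if (is.null(groups)) abort("group labels are required")
  stopifnot(length(pair) == 2)
  unknown <- setdiff(pair, unique(groups$group))
  if (length(unknown)) {
    abort(paste0("unknown group(s): ", paste(unknown, collapse = ", ")))
  }
  has_depth <- "depth" %in% names(calls)
  if (config$min_depth > 0 && !has_depth) {
    abort("min_depth > 0 requires per-call depths")
  }

  per_group <- function(g) {
    n_g <- sum(groups$group == g)
    d <- calls |>
      dplyr::semi_join(groups[groups$group == g, , drop = FALSE],
                       by = "indiv")
    if (!has_depth) d$depth <- NA_real_
    d |>
      dplyr::group_by(.data$locus) |>
      dplyr::summarise(
        n_typed = sum(!is.na(.data$a1)),
        n_alleles = dplyr::n_distinct(
          c(.data$a1[!is.na(.data$a1)], .data$a2[!is.na(.data$a2)])),
        allele = if (any(!is.na(.data$a1)))
          .data$a1[!is.na(.data$a1)][1] else NA_character_,
        mean_depth = mean(.data$depth[!is.na(.data$a1)]),
        min_depth_typed = suppressWarnings(
          min(.data$depth[!is.na(.data$a1)])),
        .groups = "drop") |>
      dplyr::mutate(fixed = .data$n_typed > 0 & .data$n_alleles == 1,
                    frac_missing = 1 - .data$n_typed / n_g)
  }
  s1 <- per_group(pair[1])
  s2 <- per_group(pair[2])
  j <- dplyr::inner_join(s1, s2, by = "locus", suffix = c("_1", "_2"))
  depth_ok <- if (config$min_depth == 0) {
    rep(TRUE, nrow(j))
  } else if (config$depth_mode == "group_mean") {
    !is.na(j$mean_depth_1) & !is.na(j$mean_depth_2) &
      j$mean_depth_1 > config$min_depth & j$mean_depth_2 > config$min_depth
  } else {
    is.finite(j$min_depth_typed_1) & is.finite(j$min_depth_typed_2) &
      j$min_depth_typed_1 > config$min_depth &
      j$min_depth_typed_2 > config$min_depth
  }
  ok <- j$fixed_1 & j$fixed_2 & !is.na(j$allele_1) & !is.na(j$allele_2) &
    j$allele_1 != j$allele_2 & depth_ok &
    j$frac_missing_1 <= config$max_group_missing &
    j$frac_missing_2 <= config$max_group_missing
  j[ok, ] |>
    dplyr::transmute(
      locus = .data$locus, group_1 = pair[1], group_2 = pair[2],
      allele_1 = .data$allele_1, allele_2 = .data$allele_2,
      mean_depth_1 = .data$mean_depth_1, mean_depth_2 = .data$mean_depth_2)
}

#' Thin diagnostic candidates to one SNP per large contig
#'
#' Candidates on contigs not strictly longer than `min_contig_length` are
#' dropped. Among surviving candidates that share a contig exactly one is
#' kept: the highest `qual`, ties broken by smallest position. Output is
#' sorted by (contig, position). This minimises linkage disequilibrium
#' between retained panel SNPs.
#'
#' @param candidates Tibble with `locus` plus `contig`, `pos`, `qual`
#'   columns (joined from locus metadata if absent, via `loci`).
#' @param contig_lengths Named numeric vector contig -> length in bp.
#' @param config A [discovery_config()].
#' @param loci Optional locus metadata to supply `contig`/`pos`/`qual`.
#' @return The thinned candidate tibble.
#' @export
thin_by_contig <- function(candidates, contig_lengths,
                           config = discovery_config(), loci = NULL) {
  if (!all(c("contig", "pos", "qual") %in% names(candidates))) {
    if (is.null(loci)) abort("candidates lack contig/pos/qual; supply loci")
    candidates <- dplyr::left_join(
      candidates, loci[c("locus", "contig", "pos", "qual")], by = "locus")
  }
  if (nrow(candidates) == 0) return(candidates)
  missing_ctg <- setdiff(unique(candidates$contig), names(contig_lengths))
  if (length(missing_ctg)) {
    abort(paste0("no length known for contig(s): ",
                 paste(missing_ctg, collapse = ", ")))
  }
  len <- unname(contig_lengths[candidates$contig])
  candidates <- candidates[len > config$min_contig_length, , drop = FALSE]
  candidates |>
    dplyr::group_by(.data$contig) |>
    dplyr::arrange(dplyr::desc(.data$qual), .data$pos,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$contig, .data$pos)
}

#' Discover a diagnostic SNP panel across all group pairs
#'
#' Runs [find_pairwise_diagnostic()] for every unordered group pair, takes
#' the union, then applies [filter_quality()] and [thin_by_contig()]. A
#' locus diagnostic for several pairs appears once, with all its pairs
#' nested in the `pairs` list-column.
#'
#' @param x A `seb_cohort` with >= 2 groups.
#' @param config A [discovery_config()].
#' @param contig_lengths Named contig length vector; defaults to the
#'   cohort's `contig_lengths` attribute.
#' @return Tibble: one row per panel locus with `locus`, `contig`, `pos`,
#'   `qual`, `n_pairs` and a `pairs` list-column (tibbles with `group_1`,
#'   `group_2`, `allele_1`, `allele_2`, `mean_depth_1`, `mean_depth_2`).
#' @export
discover_panel <- function(x, config = discovery_config(),
                           contig_lengths = NULL) {
  groups <- cohort_groups(x)
  if (is.null(groups) || dplyr::n_distinct(groups$group) < 2) {
    abort("panel discovery needs at least two groups")
  }
  contig_lengths <- contig_lengths %||% attr(x, "contig_lengths")
  if (is.null(contig_lengths)) abort("contig lengths are required")
  gnames <- unique(groups$group)
  pairs <- utils::combn(gnames, 2)
  cand <- purrr::map_dfr(seq_len(ncol(pairs)), function(p)
    find_pairwise_diagnostic(x, pairs[, p], config))
  if (nrow(cand) == 0) {
    return(tibble::tibble(locus = character(), contig = character(),
                          pos = integer(), qual = numeric(),
                          n_pairs = integer(), pairs = list()))
  }
  nested <- cand |>
    tidyr::nest(pairs = -"locus") |>
    dplyr::mutate(n_pairs = vapply(.data$pairs, nrow, integer(1))) |>
    dplyr::left_join(x$loci[c("locus", "contig", "pos", "qual")],
                     by = "locus")
  kept <- filter_quality(nested, config$min_qual)
  thin_by_contig(kept, contig_lengths, config) |>
    dplyr::select("locus", "contig", "pos", "qual", "n_pairs", "pairs")
}
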