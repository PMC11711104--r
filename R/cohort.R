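#' @keywords internal
VALID_ALLELES <- c("A", "C", "G", "T")

#' Normalize diploid genotype calls
#'
#' Sorts each allele pair lexicographically so that heterozygotes compare
#' equal regardless of input order, and propagates the MISSING sentinel: if
#' either allele is `NA` the whole call is MISSING (`NA`/`NA`).
#'
#' @param a1,a2 Character vectors of single-letter alleles (`A`, `C`, `G`,
#'   `T`) or `NA`.
#' @return A two-column tibble `a1`, `a2` with `a1 <= a2` row-wise.
#' @export
#' @examples
#' normalize_genotype(c("T", "C", NA), c("C", "C", "A"))
normalize_genotype <- function(a1, a2) {
  a1 <- toupper(as.character(a1))
  a2 <- toupper(as.character(a2))
  bad <- (!is.na(a1) & !a1 %in% VALID_ALLELES) |
    (!is.na(a2) & !a2 %in% VALID_ALLELES)
  if (any(bad)) {
    abort(paste0("invalid allele symbol(s): ",
                 paste(unique(c(a1[bad], a2[bad])), collapse = ", ")))
  }
  miss <- is.na(a1) | is.na(a2)
  lo <- ifelse(a1 <= a2, a1, a2)
  hi <- ifelse(a1 <= a2, a2, a1)
  lo[miss] <- NA_character_
  hi[miss] <- NA_character_
  tibble::tibble(a1 = lo, a2 = hi)
}

#' Genotype cohort container
#'
#' Bundles the three tables every analysis stage consumes:
#' \describe{
#'   \item{calls}{long tibble, one row per individual per locus, columns
#'     `indiv`, `locus`, `a1`, `a2` (sorted allele pair, `NA` = missing)
#'     and optionally `depth` (non-negative read count).}
#'   \item{loci}{one row per locus: `locus`, `contig`, `pos` (1-based),
#'     `ref`, `alt` (comma-separated for multi-allelic), `qual`
#'     (Phred-scaled).}
#'   \item{groups}{optional mapping `indiv` -> `group` (species unit).}
#' }
#'
#' @param calls Tibble of genotype calls as described above.
#' @param loci Optional locus metadata tibble; a minimal one is derived
#'   from `calls` when absent.
#' @param groups Optional `indiv`/`group` tibble.
#' @return An object of class `seb_cohort`.
#' @export
new_cohort <- function(calls, loci = NULL, groups = NULL) {
  stopifnot(is.data.frame(calls))
  req <- c("indiv", "locus", "a1", "a2")
  if (!all(req %in% names(calls))) {
    abort(paste0("calls must have columns: ", paste(req, collapse = ", ")))
  }
  calls <- tibble::as_tibble(calls)
  norm <- normalize_genotype(calls$a1, calls$a2)
  calls$a1 <- norm$a1
  calls$a2 <- norm$a2
  if ("depth" %in% names(calls) &&
      any(!is.na(calls$depth) & calls$depth < 0)) {
    abort("depths must be non-negative")
  }
  if (anyDuplicated(calls[c("indiv", "locus")])) {
    abort("duplicate individual x locus call")
  }
  if (is.null(loci)) {
    loci <- tibble::tibble(
      locus = unique(calls$locus), contig = NA_character_,
      pos = NA_integer_, ref = NA_character_, alt = NA_character_,
      qual = NA_real_
    )
  }
  loci <- tibble::as_tibble(loci)
  if (anyDuplicated(loci$locus)) abort("duplicate locus labels")
  missing_loci <- setdiff(unique(calls$locus), loci$locus)
  if (length(missing_loci)) {
    abort(paste0("calls reference loci absent from metadata: ",
                 paste(head(missing_loci, 5), collapse = ", ")))
  }
  if (!is.null(loci$pos) && any(!is.na(loci$pos) & loci$pos < 1)) {
    abort("positions are 1-based: pos must be >= 1")
  }
  if (!is.null(groups)) {
    groups <- tibble::as_tibble(groups)
    if (!all(c("indiv", "group") %in% names(groups))) {
      abort("groups must have columns indiv, group")
    }
    unknown <- setdiff(groups$indiv, unique(calls$indiv))
    if (length(unknown)) {
      abort(paste0("group labels for unknown individuals: ",
                   paste(head(unknown, 5), collapse = ", ")))
    }
    if (anyDuplicated(groups$indiv)) abort("individual labeled twice in groups")
  }
  structure(list(calls = calls, loci = loci, groups = groups),
            class = "seb_cohort")
}

#' @export
print.seb_cohort <- function(x, ...) {
  n_ind <- dplyr::n_distinct(x$calls$indiv)
  n_loc <- nrow(x$loci)
  cat(sprintf("<seb_cohort> %d individuals x %d loci\n", n_ind, n_loc))
  if (!is.null(x$groups)) {
    tab <- table(x$groups$group)
    cat("groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
        "\n")
  }
  n_miss <- sum(is.na(x$calls$a1))
  cat(sprintf("missing calls: %d (%.1f%%)\n", n_miss,
              100 * n_miss / nrow(x$calls)))
  invisible(x)
}

#' Extract the calls table from a cohort or pass a calls tibble through
#' @param x A `seb_cohort` or a calls tibble.
#' @return The calls tibble.
#' @export
cohort_calls <- function(x) {
  if (inherits(x, "seb_cohort")) return(x$calls)
  if (is.data.frame(x)) return(tibble::as_tibble(x))
  abort("expected a seb_cohort or a calls data frame")
}

#' @rdname cohort_calls
#' @export
cohort_groups <- function(x) {
  if (inherits(x, "seb_cohort")) return(x$groups)
  NULL
}

#' Convert a cohort to a wide genotype table
#'
#' One row per individual, one two-character genotype column per locus
#' (e.g. `"CT"`), missing calls as `"NN"`; a `group` column when labels are
#' attached.
#'
#' @param x A `seb_cohort`.
#' @return A wide tibble.
#' @export
cohort_wide <- function(x) {
  calls <- cohort_calls(x)
  wide <- calls |>
    dplyr::mutate(gt = ifelse(is.na(.data$a1), "NN",
                              paste0(.data$a1, .data$a2))) |>
    dplyr::select("indiv", "locus", "gt") |>
    tidyr::pivot_wider(names_from = "locus", values_from = "gt")
  grp <- cohort_groups(x)
  if (!is.null(grp)) {
    wide <- dplyr::left_join(grp, wide, by = "indiv")
  }
  wide
}
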