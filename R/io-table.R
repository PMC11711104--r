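#' Read a delimited genotype table
#'
#' Accepts the generic tabular genotype dialect: one row per individual, an
#' `indiv` column (or first column), an optional `group` column, and then
#' either one two-character genotype column per locus (`"CT"`, `"NN"` for
#' missing) or two single-allele columns per locus named `locus.1` /
#' `locus.2`. Header row names the loci. Unparseable genotype tokens become
#' MISSING; their count is reported in a warning and as attribute
#' `n_bad_tokens`.
#'
#' @param path Path to a CSV/TSV file (delimiter sniffed from the header).
#' @return A [new_cohort()] with groups attached when a group column exists.
#' @export
read_geno_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) abort("genotype table needs a header and >=1 row")
  delim <- if (grepl("\t", lines[1])) "\t" else ","
  cells <- strsplit(lines, delim, fixed = TRUE)
  hdr <- trimws(cells[[1]])
  widths <- lengths(cells[-1])
  if (any(widths != length(hdr))) {
    bad <- which(widths != length(hdr))[1] + 1
    abort(sprintf("ragged row %d: %d fields, header has %d",
                  bad, widths[bad - 1], length(hdr)))
  }
  body <- do.call(rbind, lapply(cells[-1], trimws))
  colnames(body) <- hdr
  df <- tibble::as_tibble(as.data.frame(body, stringsAsFactors = FALSE))

  ind_col <- if ("indiv" %in% hdr) "indiv" else hdr[1]
  grp_col <- intersect(c("group", "species", "pop"), hdr)[1]
  if (anyDuplicated(df[[ind_col]])) {
    abort(paste0("duplicated individual label: ",
                 df[[ind_col]][duplicated(df[[ind_col]])][1]))
  }
  locus_cols <- setdiff(hdr, c(ind_col, grp_col))
  if (!length(locus_cols)) abort("no locus columns found")

  paired <- grepl("\\.[12]$", locus_cols)
  n_bad <- 0L
  if (all(paired)) {
    base <- unique(sub("\\.[12]$", "", locus_cols))
    calls <- purrr::map_dfr(base, function(l) {
      a1 <- toupper(df[[paste0(l, ".1")]])
      a2 <- toupper(df[[paste0(l, ".2")]])
      ok <- a1 %in% VALID_ALLELES & a2 %in% VALID_ALLELES
      n_bad <<- n_bad + sum(!ok & !(a1 %in% c("N", "0", "-", "") &
                                      a2 %in% c("N", "0", "-", "")))
      a1[!ok] <- NA_character_
      a2[!ok] <- NA_character_
      tibble::tibble(indiv = df[[ind_col]], locus = l, a1 = a1, a2 = a2)
    })
  } else {
    calls <- purrr::map_dfr(locus_cols, function(l) {
      tok <- toupper(df[[l]])
      a1 <- substr(tok, 1, 1)
      a2 <- substr(tok, 2, 2)
      ok <- nchar(tok) == 2 & a1 %in% VALID_ALLELES & a2 %in% VALID_ALLELES
      n_bad <<- n_bad + sum(!ok & tok != "NN")
      a1[!ok] <- NA_character_
      a2[!ok] <- NA_character_
      tibble::tibble(indiv = df[[ind_col]], locus = l, a1 = a1, a2 = a2)
    })
  }
  if (n_bad > 0) {
    warn(sprintf("%d unparseable genotype token(s) set to MISSING", n_bad))
  }
  groups <- if (!is.na(grp_col)) {
    tibble::tibble(indiv = df[[ind_col]], group = df[[grp_col]])
  } else NULL
  out <- new_cohort(calls, groups = groups)
  attr(out, "n_bad_tokens") <- n_bad
  out
}

#' Write a cohort as a CSV genotype table
#'
#' Inverse of [read_geno_table()]'s two-character dialect.
#'
#' @param x A `seb_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geno_table <- function(x, path) {
  readr::write_csv(cohort_wide(x), path)
  invisible(path)
}

GENEPOP_CODE <- c(A = "01", C = "02", G = "03", T = "04")

#' Write a cohort in GENEPOP format
#'
#' Alleles are coded `01`--`04` in fixed A,C,G,T order so files are
#' bit-reproducible; MISSING is `0000`; one `Pop` block per group in group
#' order of first appearance.
#'
#' @param x A `seb_cohort` with group labels (or pass `groups`).
#' @param path Output path.
#' @param groups Optional `indiv`/`group` tibble overriding the cohort's.
#' @param title Header line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(x, path, groups = NULL,
                          title = "sebpanel genotypes") {
  calls <- cohort_calls(x)
  groups <- groups %||% cohort_groups(x)
  if (is.null(groups)) abort("GENEPOP output needs group labels")
  loci <- unique(calls$locus)
  gt <- calls |>
    dplyr::mutate(code = ifelse(
      is.na(.data$a1), "0000",
      paste0(GENEPOP_CODE[.data$a1], GENEPOP_CODE[.data$a2]))) |>
    dplyr::select("indiv", "locus", "code") |>
    tidyr::pivot_wider(names_from = "locus", values_from = "code",
                       values_fill = "0000")
  bad <- calls$a1[!is.na(calls$a1) & !calls$a1 %in% names(GENEPOP_CODE)]
  if (length(bad)) abort("allele outside A/C/G/T cannot be GENEPOP-coded")

  lines <- c(title, loci)
  for (g in unique(groups$group)) {
    lines <- c(lines, "Pop")
    inds <- groups$indiv[groups$group == g]
    rows <- gt[match(inds, gt$indiv), , drop = FALSE]
    lines <- c(lines, paste0(
      rows$indiv, " ,  ",
      apply(as.matrix(rows[, loci, drop = FALSE]), 1, paste, collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GENEPOP file written by [write_genepop()]
#'
#' Population blocks become groups `pop_1`, `pop_2`, ... in file order
#' (GENEPOP does not name populations); genotype calls round-trip exactly.
#'
#' @param path Path to a GENEPOP file with 4-digit genotype codes.
#' @return A [new_cohort()] with groups attached.
#' @export
read_genepop <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  pop_idx <- which(toupper(trimws(lines)) == "POP")
  if (!length(pop_idx)) abort("no Pop block found: not a GENEPOP file")
  loci_block <- lines[2:(pop_idx[1] - 1)]
  loci <- trimws(unlist(strsplit(loci_block, ",")))
  decode <- setNames(names(GENEPOP_CODE), GENEPOP_CODE)

  calls <- list()
  groups <- list()
  b <- 0L
  for (i in seq(pop_idx[1], length(lines))) {
    if (toupper(trimws(lines[i])) == "POP") {
      b <- b + 1L
      next
    }
    parts <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    if (length(parts) < 2) abort(sprintf("malformed GENEPOP line %d", i))
    ind <- trimws(parts[1])
    codes <- strsplit(trimws(parts[2]), "[ \t]+")[[1]]
    if (length(codes) != length(loci)) {
      abort(sprintf("line %d: %d genotypes for %d loci", i,
                    length(codes), length(loci)))
    }
    c1 <- substr(codes, 1, 2)
    c2 <- substr(codes, 3, 4)
    a1 <- unname(decode[c1])
    a2 <- unname(decode[c2])
    a1[c1 == "00"] <- NA_character_
    a2[c2 == "00"] <- NA_character_
    calls[[length(calls) + 1]] <- tibble::tibble(
      indiv = ind, locus = loci, a1 = a1, a2 = a2)
    groups[[length(groups) + 1]] <- tibble::tibble(indiv = ind,
                                                   group = paste0("pop_", b))
  }
  new_cohort(dplyr::bind_rows(calls), groups = dplyr::bind_rows(groups))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
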