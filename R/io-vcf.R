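#' Read a VCF file into a genotype cohort
#'
#' Parses a VCF v4.x file with per-sample `GT` (and optionally `DP`)
#' fields. One locus is produced per record; multi-allelic records keep all
#' alternate alleles. `./.`, `.` and half-calls such as `./1` become
#' MISSING. Phased separators (`|`) are treated as unphased and every
#' genotype is stored as a sorted allele pair. The record `QUAL` column is
#' kept as the locus quality score and `##contig` header lengths are
#' attached as the `contig_lengths` attribute.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param sample_subset Optional character vector of sample names to keep.
#' @return A [new_cohort()] object. Records whose alleles are not simple
#'   A/C/G/T SNPs are rejected; the count is available as attribute
#'   `n_rejected` and `records-in = loci-out + n_rejected`.
#' @export
read_vcf <- function(path, sample_subset = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcf@fix, stringsAsFactors = FALSE))
  if (nrow(fix) == 0) abort("VCF contains no records")
  samples <- colnames(vcf@gt)[-1]
  if (!is.null(sample_subset)) {
    unknown <- setdiff(sample_subset, samples)
    if (length(unknown)) {
      abort(paste0("sample_subset names not in VCF: ",
                   paste(unknown, collapse = ", ")))
    }
    samples <- sample_subset
  }

  ref <- toupper(fix$REF)
  alt <- toupper(fix$ALT)
  keep <- !is.na(ref) & ref %in% VALID_ALLELES & !is.na(alt) &
    vapply(strsplit(alt, ",", fixed = TRUE),
           function(a) all(a %in% VALID_ALLELES), logical(1))
  n_rejected <- sum(!keep)
  if (!any(keep)) abort("no simple SNP records in VCF")

  id <- fix$ID
  id[is.na(id) | id == "."] <- paste0(fix$CHROM, "_", fix$POS)[is.na(id) | id == "."]
  if (anyDuplicated(id[keep])) {
    id <- make.unique(id, sep = "_dup")
  }
  loci <- tibble::tibble(
    locus = id[keep],
    contig = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = ref[keep],
    alt = alt[keep],
    qual = suppressWarnings(as.numeric(fix$QUAL[keep]))
  )

  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, samples, drop = FALSE]
  has_dp <- "DP" %in% unlist(strsplit(unique(vcf@gt[, "FORMAT"]), ":"))
  dp <- if (has_dp) {
    suppressWarnings(
      vcfR::extract.gt(vcf, element = "DP",
                       as.numeric = TRUE)[keep, samples, drop = FALSE])
  } else NULL

  allele_lists <- strsplit(paste(loci$ref, loci$alt, sep = ","), ",",
                           fixed = TRUE)
  decode <- function(gts, alleles) {
    parts <- strsplit(gts, "[/|]")
    a1 <- a2 <- rep(NA_character_, length(gts))
    ok <- lengths(parts) == 2
    i1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1)))
    i2 <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= 2) p[2] else NA_character_, "")))
    typed <- ok & !is.na(i1) & !is.na(i2)
    bad_idx <- typed & (i1 >= length(alleles) | i2 >= length(alleles))
    if (any(bad_idx)) abort("GT allele index beyond ALT list")
    a1[typed] <- alleles[i1[typed] + 1]
    a2[typed] <- alleles[i2[typed] + 1]
    list(a1 = a1, a2 = a2)
  }

  calls <- purrr::map_dfr(seq_len(nrow(loci)), function(i) {
    g <- decode(unname(gt[i, ]), allele_lists[[i]])
    tibble::tibble(indiv = samples, locus = loci$locus[i],
                   a1 = g$a1, a2 = g$a2,
                   depth = if (is.null(dp)) NA_integer_ else
                     as.integer(unname(dp[i, ])))
  })
  if (is.null(dp)) calls$depth <- NULL

  out <- new_cohort(calls, loci)
  attr(out, "n_rejected") <- n_rejected
  cl <- vcf@meta[grepl("^##contig=", vcf@meta)]
  if (length(cl)) {
    ids <- sub('.*ID=([^,>]+).*', '\\1', cl)
    lens <- suppressWarnings(as.numeric(sub('.*length=([0-9]+).*', '\\1', cl)))
    attr(out, "contig_lengths") <- setNames(lens, ids)
  }
  out
}

#' Write a simulated cohort as a VCF v4.2 file
#'
#' Emits one record per locus with `GT:DP` per sample, `##contig` header
#' lines carrying the planted contig lengths, and the locus quality in the
#' `QUAL` column. [read_vcf()] inverts it exactly for genotype calls.
#'
#' @param x A `seb_cohort` whose calls carry a `depth` column.
#' @param path Output file path.
#' @param contig_lengths Named numeric vector contig -> length (bp). Taken
#'   from a simulation truth table or the cohort's `contig_lengths`
#'   attribute when omitted.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(x, path, contig_lengths = NULL) {
  calls <- cohort_calls(x)
  loci <- x$loci
  if (!"depth" %in% names(calls)) abort("cohort has no depths; VCF output requires GT:DP")
  if (is.null(contig_lengths)) contig_lengths <- attr(x, "contig_lengths")
  samples <- unique(calls$indiv)

  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=sebpanel",
    if (!is.null(contig_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
              as.integer(contig_lengths))
    },
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )

  gt_wide <- calls |>
    dplyr::left_join(loci[c("locus", "ref", "alt")], by = "locus")
  allele_idx <- function(a, ref, alt) {
    al <- strsplit(paste(ref, alt, sep = ","), ",", fixed = TRUE)
    vapply(seq_along(a), function(i) {
      if (is.na(a[i])) return(NA_integer_)
      m <- match(a[i], al[[i]])
      if (is.na(m)) abort(sprintf("allele %s not among REF/ALT of its locus", a[i]))
      m - 1L
    }, integer(1))
  }
  i1 <- allele_idx(gt_wide$a1, gt_wide$ref, gt_wide$alt)
  i2 <- allele_idx(gt_wide$a2, gt_wide$ref, gt_wide$alt)
  gt_wide$gt <- ifelse(is.na(i1), "./.", paste(i1, i2, sep = "/"))
  gt_wide$field <- paste0(gt_wide$gt, ":",
                          ifelse(is.na(gt_wide$depth), ".", gt_wide$depth))

  mat <- gt_wide |>
    dplyr::select("indiv", "locus", "field") |>
    tidyr::pivot_wider(names_from = "indiv", values_from = "field")
  mat <- mat[match(loci$locus, mat$locus), , drop = FALSE]

  body <- vapply(seq_len(nrow(loci)), function(i) {
    paste(c(loci$contig[i], loci$pos[i], loci$locus[i], loci$ref[i],
            loci$alt[i],
            ifelse(is.na(loci$qual[i]), ".", format(loci$qual[i])),
            "PASS", ".", "GT:DP",
            unlist(mat[i, samples])), collapse = "\t")
  }, character(1))

  writeLines(c(hdr, body), path)
  invisible(path)
}
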