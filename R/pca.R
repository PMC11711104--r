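#' Allele-dosage PCA of a genotype cohort
#'
#' Genotypes are coded as the count (0/1/2) of the lexicographically first
#' allele observed at each locus. Missing dosages are replaced by the
#' locus mean, columns are mean-centred (no variance scaling), and the
#' axes come from the eigendecomposition of the centred matrix. Percent
#' variance per axis is its eigenvalue over the eigenvalue sum. Axis signs
#' are fixed by making the largest-magnitude loading positive, so results
#' are reproducible. All-missing loci are dropped with a warning.
#'
#' @param x A `seb_cohort` (group labels, if present, are carried into the
#'   scores for plotting).
#' @return A list of class `seb_pca`: `scores` (tibble `indiv`, optional
#'   `group`, `PC1`, `PC2`, ...), `var_explained` (percent per axis,
#'   sums to 100), `loadings` (matrix loci x axes), `sdev`.
#' @export
pca_dosage <- function(x) {
  calls <- cohort_calls(x)
  first_allele <- calls |>
    dplyr::filter(!is.na(.data$a1)) |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(first = min(c(.data$a1, .data$a2)), .groups = "drop")
  all_missing <- setdiff(unique(calls$locus), first_allele$locus)
  if (length(all_missing)) {
    warn(sprintf("dropping %d all-missing locus/loci", length(all_missing)))
    calls <- calls[!calls$locus %in% all_missing, , drop = FALSE]
  }
  dos <- calls |>
    dplyr::left_join(first_allele, by = "locus") |>
    dplyr::mutate(dosage = ifelse(
      is.na(.data$a1), NA_real_,
      (.data$a1 == .data$first) + (.data$a2 == .data$first)))
  wide <- dos |>
    dplyr::select("indiv", "locus", "dosage") |>
    tidyr::pivot_wider(names_from = "locus", values_from = "dosage")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$indiv
  if (nrow(m) < 2) abort("PCA needs >= 2 individuals")
  # mean imputation of missing dosages
  for (j in seq_len(ncol(m))) {
    mu <- mean(m[, j], na.rm = TRUE)
    m[is.na(m[, j]), j] <- mu
  }
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  # sign convention: largest-magnitude loading positive
  for (k in seq_len(ncol(pc$rotation))) {
    jmax <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[jmax, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  ev <- pc$sdev^2
  var_explained <- 100 * ev / sum(ev)
  scores <- tibble::as_tibble(pc$x, rownames = "indiv")
  grp <- cohort_groups(x)
  if (!is.null(grp)) {
    scores <- dplyr::left_join(scores, grp, by = "indiv") |>
      dplyr::relocate("group", .after = "indiv")
  }
  structure(list(scores = scores, var_explained = var_explained,
                 loadings = pc$rotation, sdev = pc$sdev),
            class = "seb_pca")
}

#' @export
print.seb_pca <- function(x, ...) {
  cat(sprintf("<seb_pca> %d individuals x %d loci\n",
              nrow(x$scores), nrow(x$loadings)))
  k <- min(4, length(x$var_explained))
  cat("variance explained:",
      paste(sprintf("PC%d %.2f%%", seq_len(k), x$var_explained[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' @rdname pca_dosage
#' @param matrix Which component to tidy: `"scores"`, `"loadings"` or
#'   `"eigenvalues"`.
#' @param ... Unused.
#' @export
tidy.seb_pca <- function(x, matrix = c("scores", "loadings",
                                       "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = x$scores,
    loadings = tibble::as_tibble(x$loadings, rownames = "locus"),
    eigenvalues = tibble::tibble(
      PC = seq_along(x$var_explained),
      eigenvalue = x$sdev^2,
      percent = x$var_explained,
      cumulative = cumsum(x$var_explained)))
}

#' @rdname pca_dosage
#' @export
glance.seb_pca <- function(x, ...) {
  tibble::tibble(
    n_indiv = nrow(x$scores),
    n_loci = nrow(x$loadings),
    pc1_pct = x$var_explained[1],
    pc2_pct = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_)
}

#' @rdname pca_dosage
#' @param object A `seb_pca`.
#' @param axes Two axis numbers to plot.
#' @export
autoplot.seb_pca <- function(object, axes = c(1, 2), ...) {
  sc <- object$scores
  xcol <- paste0("PC", axes[1])
  ycol <- paste0("PC", axes[2])
  p <- ggplot2::ggplot(sc, ggplot2::aes(.data[[xcol]], .data[[ycol]]))
  p <- if ("group" %in% names(sc)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
  p +
    ggplot2::labs(
      x = sprintf("PC%d (%.2f%%)", axes[1], object$var_explained[axes[1]]),
      y = sprintf("PC%d (%.2f%%)", axes[2], object$var_explained[axes[2]]),
      colour = "group") +
    ggplot2::theme_minimal()
}

#' Heterozygosity overview plot for a locus summary table
#'
#' Observed vs expected heterozygosity per locus; points above the
#' diagonal are heterozygote-deficient (positive F), the Wahlund signature
#' of pooled isolated groups.
#'
#' @param summary A [summary_table()] tibble.
#' @return A ggplot.
#' @export
plot_heterozygosity <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(.data$He, .data$Ho)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$F)) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1), na.value = "grey70") +
    ggplot2::coord_equal(xlim = c(0, 0.55), ylim = c(0, 0.55)) +
    ggplot2::labs(x = expression(H[E]), y = expression(H[O]),
                  colour = expression(F[IS])) +
    ggplot2::theme_minimal()
}
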