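#' Cavalli-Sforza & Edwards chord distance between two groups
#'
#' Per locus `l`, the allele-frequency similarity is
#' `f_l = sum_j sqrt(x_lj * y_lj)` (clipped to `[0, 1]`), the per-locus
#' chord distance `d_l = (2/pi) * sqrt(2 * (1 - f_l))`, and the multilocus
#' distance is by default the arithmetic mean of `d_l` over loci. The
#' variant that averages the similarity inside the square root
#' (`aggregate = "mean_similarity"`) is offered because published
#' implementations differ.
#'
#' @param freqs_x,freqs_y Tibbles `locus`, `allele`, `freq` for the two
#'   groups; each locus's frequencies sum to 1. Locus lists must match.
#' @param aggregate `"mean_distance"` (default) or `"mean_similarity"`.
#' @return A single non-negative distance; 0 when the tables are
#'   identical.
#' @export
chord_distance <- function(freqs_x, freqs_y,
                           aggregate = c("mean_distance",
                                         "mean_similarity")) {
  aggregate <- match.arg(aggregate)
  lx <- sort(unique(freqs_x$locus))
  ly <- sort(unique(freqs_y$locus))
  if (!identical(lx, ly)) abort("locus lists differ between the two groups")
  j <- dplyr::full_join(
    freqs_x[c("locus", "allele", "freq")],
    freqs_y[c("locus", "allele", "freq")],
    by = c("locus", "allele"), suffix = c("_x", "_y")) |>
    tidyr::replace_na(list(freq_x = 0, freq_y = 0))
  f <- j |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(f = sum(sqrt(.data$freq_x * .data$freq_y)),
                     .groups = "drop")
  fl <- pmin(pmax(f$f, 0), 1)
  if (aggregate == "mean_distance") {
    mean((2 / pi) * sqrt(2 * (1 - fl)))
  } else {
    (2 / pi) * sqrt(2 * (1 - mean(fl)))
  }
}

#' Pairwise chord-distance matrix between all groups
#'
#' @param freqs A [group_allele_freqs()] table. Loci untyped in any group
#'   are dropped with a warning so all groups share the locus list.
#' @param aggregate Passed to [chord_distance()].
#' @return A symmetric labelled matrix with zero diagonal.
#' @export
chord_dist_matrix <- function(freqs, aggregate = "mean_distance") {
  gnames <- unique(freqs$group)
  shared <- freqs |>
    dplyr::distinct(.data$group, .data$locus) |>
    dplyr::count(.data$locus) |>
    dplyr::filter(.data$n == length(gnames)) |>
    dplyr::pull(.data$locus)
  dropped <- setdiff(unique(freqs$locus), shared)
  if (length(dropped)) {
    warn(sprintf("%d locus/loci untyped in some group dropped", length(dropped)))
  }
  freqs <- freqs[freqs$locus %in% shared, , drop = FALSE]
  d <- matrix(0, length(gnames), length(gnames),
              dimnames = list(gnames, gnames))
  for (i in seq_along(gnames)) {
    for (k in seq_len(i - 1)) {
      d[i, k] <- d[k, i] <- chord_distance(
        freqs[freqs$group == gnames[i], ],
        freqs[freqs$group == gnames[k], ], aggregate)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration: at each step the pair minimising
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is joined; branch
#' lengths come from the standard formulas. Ties in `Q` are broken by the
#' lexicographically smallest (sorted) label pair, so the result is fully
#' deterministic. Negative branch lengths are floored at 0 unless
#' `floor_negative = FALSE` (additive matrices are recovered exactly with
#' the unfloored values).
#'
#' @param d Symmetric non-negative matrix with zero diagonal and dimnames,
#'   >= 3 taxa (or a `dist`).
#' @param floor_negative Floor negative branch lengths at zero.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d, floor_negative = TRUE) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d))) abort("distance matrix needs dimnames")
  if (nrow(d) < 3) abort("neighbor-joining needs >= 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8)) abort("distance matrix not symmetric")
  if (any(diag(d) < 0) || any(abs(diag(d)) > 1e-12)) {
    abort("distance matrix must have a zero diagonal")
  }

  labels <- rownames(d)
  # cluster identity for tie-breaking: smallest leaf label in the cluster
  key <- labels
  nwk <- labels
  fl <- function(v) if (floor_negative) max(v, 0) else v
  fmt <- function(x) sprintf("%.17g", x)

  while (nrow(d) > 3) {
    n <- nrow(d)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    pair_key <- apply(best, 1, function(ij) {
      ks <- sort(c(key[ij[1]], key[ij[2]]))
      paste(ks, collapse = "\r")
    })
    pick <- best[order(pair_key)[1], ]
    i <- pick[1]; j <- pick[2]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- d[i, j] - vi
    new_nwk <- paste0("(", nwk[i], ":", fmt(fl(vi)), ",",
                      nwk[j], ":", fmt(fl(vj)), ")")
    new_key <- min(key[i], key[j])
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    key <- c(key[keep], new_key)
    nwk <- c(nwk[keep], new_nwk)
    d <- d2
  }
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  s <- paste0("(", nwk[1], ":", fmt(fl(v1)), ",",
              nwk[2], ":", fmt(fl(v2)), ",",
              nwk[3], ":", fmt(fl(v3)), ");")
  ape::read.tree(text = s)
}

#' Leaf bipartitions induced by the internal edges of an unrooted tree
#'
#' Each edge whose child is an internal node defines a split of the leaf
#' set; the side not containing the first tip label is canonicalised as a
#' sorted `|`-joined string. Trivial (single-leaf) splits are excluded.
#'
#' @param tree An `ape::phylo`.
#' @return Tibble: `node` (internal node id), `split` (canonical string).
#' @export
tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  edge <- tree$edge
  desc <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    unlist(lapply(edge[edge[, 1] == node, 2], desc))
  }
  internal_children <- edge[edge[, 2] > n, 2]
  if (!length(internal_children)) {
    return(tibble::tibble(node = integer(), split = character()))
  }
  ref <- sort(tree$tip.label)[1]
  out <- purrr::map_dfr(internal_children, function(nd) {
    tips <- desc(nd)
    side <- if (ref %in% tips) setdiff(tree$tip.label, tips) else tips
    tibble::tibble(node = nd, split = paste(sort(side), collapse = "|"))
  })
  size <- vapply(strsplit(out$split, "|", fixed = TRUE), length, integer(1))
  out[size >= 2 & size <= n - 2, , drop = FALSE]
}

#' Neighbor-joining tree with locus-bootstrap node support
#'
#' Builds the tree from full-data group allele frequencies and chord
#' distances, then for each of `n_boot` replicates resamples loci with
#' replacement (same count), recomputes frequencies, chord distances and
#' the NJ tree, and scores each internal edge of the original tree by the
#' percentage of replicate trees containing the same leaf bipartition.
#'
#' @param x A `seb_cohort` with >= 3 groups and >= 2 loci.
#' @param n_boot Number of bootstrap replicates (>= 1); the published
#'   protocol uses 1000.
#' @param seed Integer seed; supports are reproducible from it.
#' @param aggregate Chord-distance aggregation, see [chord_distance()].
#' @return A list of class `seb_tree`: `tree` (phylo, node labels carry
#'   integer support), `support` (tibble `split`/`support`), `dist`
#'   (chord-distance matrix), `n_boot`.
#' @export
bootstrap_support <- function(x, n_boot = 1000, seed = 1L,
                              aggregate = "mean_distance") {
  if (n_boot < 1) abort("n_boot must be >= 1")
  groups <- cohort_groups(x)
  if (is.null(groups) || dplyr::n_distinct(groups$group) < 3) {
    abort("bootstrap tree needs >= 3 groups")
  }
  freqs <- suppressWarnings(group_allele_freqs(x))
  gnames <- unique(freqs$group)
  shared <- freqs |>
    dplyr::distinct(.data$group, .data$locus) |>
    dplyr::count(.data$locus) |>
    dplyr::filter(.data$n == length(gnames)) |>
    dplyr::pull(.data$locus)
  if (length(shared) < 2) abort("need >= 2 loci typed in every group")
  freqs <- freqs[freqs$locus %in% shared, , drop = FALSE]

  d0 <- chord_dist_matrix(freqs, aggregate)
  tree <- nj_tree(d0)
  splits0 <- tree_splits(tree)

  freq_by_locus <- split(freqs, freqs$locus)
  withr::local_seed(seed)
  hits <- setNames(numeric(nrow(splits0)), splits0$split)
  for (b in seq_len(n_boot)) {
    take <- sample(shared, length(shared), replace = TRUE)
    # resampled duplicates count as distinct loci
    fb <- purrr::map_dfr(seq_along(take), function(i) {
      df <- freq_by_locus[[take[i]]]
      df$locus <- sprintf("bs%04d", i)
      df
    })
    db <- chord_dist_matrix(fb, aggregate)
    sb <- tree_splits(nj_tree(db))$split
    hits[splits0$split %in% sb] <- hits[splits0$split %in% sb] + 1
  }
  support <- tibble::tibble(split = splits0$split,
                            support = 100 * unname(hits) / n_boot)

  n <- length(tree$tip.label)
  node_lab <- rep("", tree$Nnode)
  for (i in seq_len(nrow(splits0))) {
    node_lab[splits0$node[i] - n] <-
      as.character(round(support$support[i]))
  }
  tree$node.label <- node_lab
  structure(list(tree = tree, support = support, dist = d0,
                 n_boot = n_boot), class = "seb_tree")
}

#' @export
print.seb_tree <- function(x, ...) {
  cat(sprintf("<seb_tree> %d groups, %d bootstrap replicates\n",
              length(x$tree$tip.label), x$n_boot))
  print(x$support)
  invisible(x)
}

#' @export
tidy.seb_tree <- function(x, ...) x$support

#' @export
glance.seb_tree <- function(x, ...) {
  tibble::tibble(n_groups = length(x$tree$tip.label),
                 n_boot = x$n_boot,
                 min_support = min(x$support$support),
                 max_dist = max(x$dist))
}

#' Plot a bootstrap-supported NJ tree
#' @param x A `seb_tree`.
#' @param ... Passed to `ape::plot.phylo`.
#' @return The `seb_tree`, invisibly.
#' @export
plot.seb_tree <- function(x, ...) {
  ape::plot.phylo(x$tree, type = "unrooted", ...)
  ape::nodelabels(x$tree$node.label, frame = "none", adj = c(1.1, -0.4))
  invisible(x)
}

#' Write a tree (with support labels) as Newick
#'
#' Branch lengths and integer internal-node support labels; the output of
#' write -> read -> write is byte-stable.
#'
#' @param tree An `ape::phylo` or `seb_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "seb_tree")) tree <- tree$tree
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Path to a Newick file.
#' @return An `ape::phylo`.
#' @export
read_newick <- function(path) ape::read.tree(path)
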