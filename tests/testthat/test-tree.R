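freq_tbl <- function(locus, alleles, freqs) {
  tibble::tibble(locus = locus, allele = alleles, freq = freqs)
}

test_that("chord distance: identity, closed form, symmetry, monotonicity", {
  fx <- freq_tbl(rep(c("L1", "L2"), each = 2), rep(c("A", "C"), 2),
                 c(0.3, 0.7, 0.9, 0.1))
  expect_equal(chord_distance(fx, fx), 0)
  # one reciprocally fixed locus: D = (2/pi) * sqrt(2)
  x <- freq_tbl("L", c("A", "C"), c(1, 0))
  y <- freq_tbl("L", c("A", "C"), c(0, 1))
  expect_equal(chord_distance(x, y), (2 / pi) * sqrt(2), tolerance = 1e-12)
  # symmetry on random tables
  withr::with_seed(4, {
    for (i in 1:5) {
      p <- runif(2)
      fa <- freq_tbl(rep(c("L1", "L2"), each = 2), rep(c("A", "G"), 2),
                     c(p[1], 1 - p[1], p[2], 1 - p[2]))
      q <- runif(2)
      fb <- freq_tbl(rep(c("L1", "L2"), each = 2), rep(c("A", "G"), 2),
                     c(q[1], 1 - q[1], q[2], 1 - q[2]))
      expect_equal(chord_distance(fa, fb), chord_distance(fb, fa))
    }
  })
  # monotone in |p1 - p2| for a single biallelic locus
  d_of <- function(p1, p2) chord_distance(
    freq_tbl("L", c("A", "C"), c(p1, 1 - p1)),
    freq_tbl("L", c("A", "C"), c(p2, 1 - p2)))
  gaps <- c(0, 0.2, 0.5, 0.8, 1)
  d <- vapply(gaps, function(g) d_of(0.5 + g / 2, 0.5 - g / 2), numeric(1))
  expect_true(all(diff(d) > -1e-12))
  expect_error(chord_distance(x, freq_tbl("OTHER", c("A", "C"), c(0, 1))),
               "locus lists differ")
  # the similarity-averaging variant differs but agrees at the extremes
  expect_equal(chord_distance(x, y, aggregate = "mean_similarity"),
               (2 / pi) * sqrt(2), tolerance = 1e-12)
})

test_that("neighbor-joining recovers closed forms and additive trees", {
  # 3 taxa: star with v_i = (d(i,j) + d(i,k) - d(j,k)) / 2
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- nj_tree(d3)
  expect_equal(sort(tr3$tip.label), c("A", "B", "C"))
  v <- setNames(tr3$edge.length[match(1:3, tr3$edge[, 2])], tr3$tip.label)
  expect_equal(unname(v[c("A", "B", "C")]), c(1, 2, 3))

  # additive 4-taxon matrix from a hand-drawn tree:
  # ((A:1,B:2):1.5,(C:3,D:4)) with internal edge 1.5
  d4 <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                        c("A", "B", "C", "D")))
  d4["A", "B"] <- d4["B", "A"] <- 3
  d4["A", "C"] <- d4["C", "A"] <- 1 + 1.5 + 3
  d4["A", "D"] <- d4["D", "A"] <- 1 + 1.5 + 4
  d4["B", "C"] <- d4["C", "B"] <- 2 + 1.5 + 3
  d4["B", "D"] <- d4["D", "B"] <- 2 + 1.5 + 4
  d4["C", "D"] <- d4["D", "C"] <- 7
  tr4 <- nj_tree(d4, floor_negative = FALSE)
  # path-length oracle: pairwise tree distances equal the input exactly
  path_d <- ape::cophenetic.phylo(tr4)[rownames(d4), colnames(d4)]
  expect_equal(path_d, d4, tolerance = 1e-12)
  expect_equal(tree_splits(tr4)$split, "C|D")

  # additive 6-taxon matrix, cross-checked against the reference NJ
  withr::with_seed(11, {
    true_tree <- ape::rtree(6, br = function(n) runif(n, 0.2, 1))
  })
  true_tree <- ape::unroot(true_tree)
  d6 <- ape::cophenetic.phylo(true_tree)
  tr6 <- nj_tree(d6, floor_negative = FALSE)
  expect_equal(ape::cophenetic.phylo(tr6)[rownames(d6), colnames(d6)],
               d6, tolerance = 1e-10)
  ref <- ape::nj(d6)
  expect_equal(ape::dist.topo(ape::unroot(tr6), ape::unroot(ref)), 0,
               ignore_attr = TRUE)

  bad <- d3; bad[1, 2] <- 99
  expect_error(nj_tree(bad), "symmetric")
  expect_error(nj_tree(d3[1:2, 1:2]), ">= 3 taxa")
})

test_that("bootstrap supports reach 100% on fully separated groups", {
  ch <- fully_separated_cohort(n_loci = 30, n_per_group = 10)
  bt <- bootstrap_support(ch, n_boot = 100, seed = 3)
  # unrooted 4-leaf tree: exactly one internal bipartition
  expect_equal(nrow(bt$support), 1)
  expect_equal(bt$support$support, 100)
  # all pairwise chord distances at the fixed-difference maximum
  off <- bt$dist[upper.tri(bt$dist)]
  expect_equal(off, rep((2 / pi) * sqrt(2), 6), tolerance = 1e-12)
})

test_that("bootstrap supports are deterministic and order-invariant", {
  sim <- simulate_cohort(sim_config(missing_rate = 0, error_rate = 0,
                                    seed = 19))
  bt1 <- bootstrap_support(sim$cohort, n_boot = 30, seed = 5)
  bt2 <- bootstrap_support(sim$cohort, n_boot = 30, seed = 5)
  expect_equal(bt1$support, bt2$support)
  # permuting call rows (individual and locus order) changes nothing
  shuf <- sim$cohort
  withr::with_seed(2, ord <- sample(nrow(shuf$calls)))
  shuf2 <- new_cohort(shuf$calls[ord, ], shuf$loci, shuf$groups)
  bt3 <- bootstrap_support(shuf2, n_boot = 30, seed = 5)
  expect_equal(dplyr::arrange(bt1$support, split),
               dplyr::arrange(bt3$support, split))
})

test_that("Newick output carries lengths and supports and is byte-stable", {
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(nj_tree(d3), path)
  txt <- readLines(path)
  expect_match(txt, "^\\(.*A:.*B:.*C:.*\\);$")

  ch <- fully_separated_cohort(n_loci = 10, n_per_group = 5)
  bt <- bootstrap_support(ch, n_boot = 20, seed = 1)
  write_newick(bt, path)
  expect_match(readLines(path), "\\)100")  # integer support label
  tr <- read_newick(path)
  path2 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path2)
  expect_identical(readLines(path), readLines(path2))
})
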