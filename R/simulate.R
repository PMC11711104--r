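#' Simulation configuration for a multi-species genotype cohort
#'
#' The defaults emulate a MassArray-scale redfish panel cohort: four
#' reproductively isolated groups of 30 fish, three reciprocally fixed
#' (diagnostic) loci planted per group pair, 40 shared polymorphic loci,
#' overdispersed ddRAD-like read depths around 40x, 2% missing calls and a
#' 0.2% per-call genotyping error.
#'
#' @param groups Named integer vector: group name -> number of individuals.
#' @param n_diagnostic_per_pair Diagnostic loci planted per unordered group
#'   pair (reciprocally fixed for alternative alleles in that pair,
#'   polymorphic at 0.5 elsewhere).
#' @param n_shared Non-diagnostic polymorphic loci shared by all groups.
#' @param shared_freq_divergence Concentration (>0) of the Beta spread of
#'   per-group allele frequencies around a common ancestral frequency at
#'   shared loci; larger = less between-group divergence.
#' @param depth_mean Expected reads per call (x coverage).
#' @param depth_dispersion Negative-binomial size parameter; smaller =
#'   more overdispersed coverage.
#' @param missing_rate Per-call probability of a missing genotype.
#' @param error_rate Per-call probability that the true genotype is
#'   replaced by a uniformly random genotype over the locus alleles
#'   (possibly the same one).
#' @param contig_length_range Length-2 integer vector (bp); each locus sits
#'   on its own contig with length drawn uniformly from this range.
#' @param seed Integer seed; every draw is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(groups = c(mentella = 30, norvegicusA = 30,
                                  norvegicusB = 30, viviparus = 30),
                       n_diagnostic_per_pair = 3,
                       n_shared = 40,
                       shared_freq_divergence = 50,
                       depth_mean = 40,
                       depth_dispersion = 5,
                       missing_rate = 0.02,
                       error_rate = 0.002,
                       contig_length_range = c(25000L, 100000L),
                       seed = 1L) {
  stopifnot(length(groups) >= 1, all(groups >= 1),
            n_diagnostic_per_pair >= 0, n_shared >= 0,
            shared_freq_divergence > 0, depth_mean > 0,
            depth_dispersion > 0,
            missing_rate >= 0, missing_rate <= 1,
            error_rate >= 0, error_rate <= 1,
            length(contig_length_range) == 2,
            contig_length_range[1] <= contig_length_range[2])
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    abort("groups must be a named vector: name -> n individuals")
  }
  structure(list(
    groups = groups, n_diagnostic_per_pair = n_diagnostic_per_pair,
    n_shared = n_shared, shared_freq_divergence = shared_freq_divergence,
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    missing_rate = missing_rate, error_rate = error_rate,
    contig_length_range = as.integer(contig_length_range),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a multi-species genotype cohort with planted diagnostic loci
#'
#' Genotypes are drawn per individual per locus as two independent allele
#' draws from the individual's group frequencies (Hardy-Weinberg within
#' group). Read depths come from a negative binomial (mean
#' `depth_mean`, size `depth_dispersion`). The error process (uniform
#' random genotype replacement) and then the missing process are applied
#' after the genotype draw. Each locus sits on its own contig with a
#' uniformly drawn length, and a high quality score (600-3000) emulating
#' post-filter variant calls.
#'
#' @param config A [sim_config()].
#' @return A list of class `seb_sim` with elements `cohort` (a
#'   [new_cohort()] incl. groups, with `contig_lengths` attribute),
#'   `truth_loci` (tibble: locus, role `diagnostic`/`shared`, `pair_1`,
#'   `pair_2`, contig, contig_length) and `truth_freqs` (tibble: locus,
#'   group, allele, freq — the true generating frequencies).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  gnames <- names(config$groups)
  if (length(gnames) < 2 && config$n_diagnostic_per_pair > 0) {
    abort("diagnostic loci need at least two groups")
  }
  withr::local_seed(config$seed)

  pairs <- if (length(gnames) >= 2) utils::combn(gnames, 2) else
    matrix(character(0), nrow = 2)
  n_diag <- config$n_diagnostic_per_pair * ncol(pairs)
  n_loci <- n_diag + config$n_shared
  if (n_loci == 0) abort("config yields zero loci")
  locus_ids <- sprintf("SNP%03d", seq_len(n_loci))

  # true per-group allele frequencies, one row per locus x group x allele
  truth_freqs <- list()
  truth_loci <- list()
  k <- 0L
  if (n_diag > 0) {
    for (p in seq_len(ncol(pairs))) {
      for (j in seq_len(config$n_diagnostic_per_pair)) {
        k <- k + 1L
        ab <- sample(VALID_ALLELES, 2)
        fr <- purrr::map_dfr(gnames, function(g) {
          f <- if (g == pairs[1, p]) c(1, 0) else
            if (g == pairs[2, p]) c(0, 1) else c(0.5, 0.5)
          tibble::tibble(locus = locus_ids[k], group = g,
                         allele = ab, freq = f)
        })
        truth_freqs[[k]] <- fr
        truth_loci[[k]] <- tibble::tibble(
          locus = locus_ids[k], role = "diagnostic",
          pair_1 = pairs[1, p], pair_2 = pairs[2, p])
      }
    }
  }
  for (j in seq_len(config$n_shared)) {
    k <- k + 1L
    ab <- sample(VALID_ALLELES, 2)
    p_anc <- runif(1, 0.2, 0.8)
    c0 <- config$shared_freq_divergence
    fr <- purrr::map_dfr(gnames, function(g) {
      pg <- rbeta(1, p_anc * c0, (1 - p_anc) * c0)
      tibble::tibble(locus = locus_ids[k], group = g,
                     allele = ab, freq = c(pg, 1 - pg))
    })
    truth_freqs[[k]] <- fr
    truth_loci[[k]] <- tibble::tibble(
      locus = locus_ids[k], role = "shared",
      pair_1 = NA_character_, pair_2 = NA_character_)
  }
  truth_freqs <- dplyr::bind_rows(truth_freqs)
  truth_loci <- dplyr::bind_rows(truth_loci)

  contig <- sprintf("ctg%03d", seq_len(n_loci))
  clen <- as.integer(round(runif(n_loci, config$contig_length_range[1],
                                 config$contig_length_range[2])))
  truth_loci$contig <- contig
  truth_loci$contig_length <- clen

  loci <- tibble::tibble(
    locus = locus_ids, contig = contig,
    pos = as.integer(round(runif(n_loci, 1, clen))),
    qual = round(runif(n_loci, 600, 3000), 1)
  )

  indiv <- unlist(purrr::map2(gnames, config$groups, function(g, n)
    sprintf("%s_%02d", g, seq_len(n))), use.names = FALSE)
  groups <- tibble::tibble(
    indiv = indiv,
    group = rep(gnames, times = config$groups))

  # two independent allele draws per call (HWE within group)
  freq_wide <- truth_freqs |>
    dplyr::group_by(.data$locus, .data$group) |>
    dplyr::summarise(alleles = list(.data$allele), probs = list(.data$freq),
                     .groups = "drop")
  calls <- tidyr::expand_grid(indiv = indiv, locus = locus_ids) |>
    dplyr::left_join(groups, by = "indiv") |>
    dplyr::left_join(freq_wide, by = c("locus", "group"))
  draw <- function(alleles, probs) sample(alleles, 2, replace = TRUE,
                                          prob = probs)
  gts <- purrr::map2(calls$alleles, calls$probs, draw)
  calls$a1 <- vapply(gts, `[`, "", 1)
  calls$a2 <- vapply(gts, `[`, "", 2)

  # error process: uniform random genotype over the locus allele set
  err <- runif(nrow(calls)) < config$error_rate
  if (any(err)) {
    repl <- purrr::map(calls$alleles[err],
                       function(a) sample(a, 2, replace = TRUE))
    calls$a1[err] <- vapply(repl, `[`, "", 1)
    calls$a2[err] <- vapply(repl, `[`, "", 2)
  }
  # missing process
  miss <- runif(nrow(calls)) < config$missing_rate
  calls$a1[miss] <- NA_character_
  calls$a2[miss] <- NA_character_

  calls$depth <- rnbinom(nrow(calls), size = config$depth_dispersion,
                         mu = config$depth_mean)
  calls <- calls |>
    dplyr::select("indiv", "locus", "a1", "a2", "depth")

  # REF = lexicographically smaller planted allele, ALT = the other
  allele_pairs <- truth_freqs |>
    dplyr::distinct(.data$locus, .data$allele) |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(ref = sort(.data$allele)[1],
                     alt = sort(.data$allele)[2], .groups = "drop")
  loci <- dplyr::left_join(loci, allele_pairs, by = "locus") |>
    dplyr::select("locus", "contig", "pos", "ref", "alt", "qual")

  cohort <- new_cohort(calls, loci, groups)
  attr(cohort, "contig_lengths") <- setNames(as.numeric(clen), contig)
  structure(list(cohort = cohort, truth_loci = truth_loci,
                 truth_freqs = truth_freqs, config = config),
            class = "seb_sim")
}

#' @export
print.seb_sim <- function(x, ...) {
  cat("<seb_sim> simulated cohort\n")
  print(x$cohort)
  cat(sprintf("loci: %d diagnostic, %d shared\n",
              sum(x$truth_loci$role == "diagnostic"),
              sum(x$truth_loci$role == "shared")))
  invisible(x)
}
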