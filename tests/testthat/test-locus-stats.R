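test_that("allele frequencies count 2N draws from typed calls", {
  calls <- calls_from_wide(list(i1 = c(L = "CC"), i2 = c(L = "CT"),
                                i3 = c(L = "TT")))
  f <- allele_freqs(calls)
  expect_equal(f$freq, c(0.5, 0.5))
  f2 <- allele_freqs(calls_from_wide(list(i1 = c(L = "CC"),
                                          i2 = c(L = "CC"))))
  expect_equal(f2$freq, 1)
  # missing calls are excluded from the denominator
  calls$a1[3] <- NA; calls$a2[3] <- NA
  f3 <- allele_freqs(calls)
  expect_equal(f3$freq[f3$allele == "C"], 0.75)
  expect_error(allele_freqs(calls_from_wide(list(i1 = c(L = "NN")))),
               "MISSING|typed")
})

test_that("frequencies of a large simulated sample sit within 3 SE", {
  withr::with_seed(77, {
    n <- 10000
    a <- ifelse(runif(n) < 0.25, "A", "G")
    b <- ifelse(runif(n) < 0.25, "A", "G")
  })
  calls <- tibble::tibble(indiv = sprintf("i%05d", 1:10000), locus = "L",
                          a1 = pmin(a, b), a2 = pmax(a, b))
  f <- allele_freqs(calls)
  se <- sqrt(0.25 * 0.75 / 20000)
  expect_lt(abs(f$freq[f$allele == "A"] - 0.25), 3 * se)
})

test_that("locus summary reproduces the published statistic definitions", {
  # MAF 0.485 -> He = 0.500 at 3 d.p.; MAF 0.027 -> He 0.053 (reference
  # panel rows), using the plain 1 - sum(p^2) gene diversity
  expect_equal(round(gene_diversity(c(0.485, 0.515)), 3), 0.500)
  expect_equal(round(gene_diversity(c(0.027, 0.973)), 3), 0.053)
  expect_equal(round(gene_diversity(c(0.030, 0.970)), 3), 0.058)
  # complete heterozygote deficiency: Ho = 0, He > 0 -> F = 1
  calls <- calls_from_wide(list(i1 = c(L = "CC"), i2 = c(L = "CC"),
                                i3 = c(L = "TT")))
  s <- locus_summary(calls)
  expect_equal(s$Ho, 0)
  expect_equal(s$F, 1)
  expect_equal(s$MAF, 1 / 3)
  # monomorphic: Ho = He = 0, F undefined, MAF = 0, p = 1
  m <- locus_summary(calls_from_wide(list(i1 = c(L = "AA"),
                                          i2 = c(L = "AA"))))
  expect_equal(m$Ho, 0)
  expect_equal(m$He, 0)
  expect_true(is.na(m$F))
  expect_equal(m$MAF, 0)
  expect_equal(m$hwe_p, 1)
})

test_that("He and F identities hold across random biallelic loci", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      n <- sample(5:60, 1)
      p <- runif(1, 0.05, 0.95)
      a1 <- ifelse(runif(n) < p, "A", "T")
      a2 <- ifelse(runif(n) < p, "A", "T")
      calls <- tibble::tibble(indiv = sprintf("i%02d", 1:n), locus = "L",
                              a1 = pmin(a1, a2), a2 = pmax(a1, a2))
      s <- locus_summary(calls)
      if (s$Na == 2) {
        expect_equal(s$He, 2 * s$MAF * (1 - s$MAF), tolerance = 1e-12)
      }
      if (!is.na(s$F) && abs(s$Ho - s$He) < 1e-12) expect_equal(s$F, 0)
    }
  })
})

test_that("exact HWE p-values match the enumeration oracle", {
  # complete heterozygote deficiency
  expect_lt(hwe_exact_test(25, 0, 25), 0.001)
  # modal configuration
  expect_equal(hwe_exact_test(1, 2, 1), 1)
  # all heterozygous, 2 individuals: matches brute force
  expect_equal(hwe_exact_test(0, 2, 0), hwe_oracle(0, 2, 0))
  # monomorphic convention
  expect_equal(hwe_exact_test(7, 0, 0), 1)
  # spot agreement across asymmetric configurations
  for (cfg in list(c(3, 1, 9), c(0, 5, 2), c(10, 2, 0), c(4, 4, 4))) {
    expect_equal(hwe_exact_test(cfg[1], cfg[2], cfg[3]),
                 hwe_oracle(cfg[1], cfg[2], cfg[3]), tolerance = 1e-9)
  }
})

test_that("LD permutation test hits its floor, ceiling and type-I rate", {
  withr::with_seed(9, {
    gt <- sample(c("AA", "AG", "GG"), 50, replace = TRUE)
  })
  calls <- dplyr::bind_rows(
    tibble::tibble(indiv = sprintf("i%02d", 1:50), locus = "L1",
                   a1 = substr(gt, 1, 1), a2 = substr(gt, 2, 2)),
    tibble::tibble(indiv = sprintf("i%02d", 1:50), locus = "L2",
                   a1 = substr(gt, 1, 1), a2 = substr(gt, 2, 2)))
  # two identical columns: minimum attainable p
  res <- ld_permutation_test(calls, "L1", "L2", n_perm = 999, seed = 1)
  expect_equal(res$p_value, 0.001)
  # reproducible from seed
  res2 <- ld_permutation_test(calls, "L1", "L2", n_perm = 999, seed = 1)
  expect_equal(res, res2)
  # monomorphic column -> p = 1
  mono <- dplyr::bind_rows(
    calls[calls$locus == "L1", ],
    tibble::tibble(indiv = sprintf("i%02d", 1:50), locus = "L2",
                   a1 = "C", a2 = "C"))
  expect_equal(ld_permutation_test(mono, "L1", "L2", n_perm = 100)$p_value, 1)
})

test_that("LD test type-I error is nominal for independent loci", {
  n_pairs <- 200
  reject <- withr::with_seed(123, {
    vapply(seq_len(n_pairs), function(i) {
      mk <- function(l) {
        p <- runif(1, 0.3, 0.7)
        x <- ifelse(runif(40) < p, "A", "C")
        y <- ifelse(runif(40) < p, "A", "C")
        tibble::tibble(indiv = sprintf("i%02d", 1:40), locus = l,
                       a1 = pmin(x, y), a2 = pmax(x, y))
      }
      calls <- dplyr::bind_rows(mk("L1"), mk("L2"))
      ld_permutation_test(calls, "L1", "L2", n_perm = 199,
                          seed = i)$p_value <= 0.05
    }, logical(1))
  })
  se <- sqrt(0.05 * 0.95 / n_pairs)
  expect_lt(abs(mean(reject) - 0.05), 3 * se + 0.005)
})

test_that("summary table has the panel-report layout and Wahlund signal", {
  sim <- simulate_cohort(sim_config(missing_rate = 0, error_rate = 0,
                                    seed = 14))
  path <- withr::local_tempfile(fileext = ".csv")
  st <- summary_table(sim$cohort, path = path)
  expect_equal(nrow(st), 58)
  hdr <- readLines(path, n = 1)
  expect_equal(hdr, "Locus,N,Na,Ho,He,F,Signif,MAF,A1,A2")
  # F prints as exactly 1 whenever Ho = 0 with He > 0
  z <- st[st$Ho == 0 & st$He > 0, ]
  if (nrow(z)) expect_true(all(z$F == 1))
  # Wahlund construction: pooling two internally-HWE groups reciprocally
  # fixed at a locus yields a strong heterozygote deficiency (F > 0.9)
  sim2 <- simulate_cohort(sim_config(
    groups = c(a = 20, b = 20), n_diagnostic_per_pair = 3, n_shared = 0,
    missing_rate = 0, error_rate = 0, seed = 15))
  st2 <- summary_table(sim2$cohort)
  expect_true(all(st2$F > 0.9))
  expect_true(all(st2$Signif == "***"))
  # significance stars follow the p-value bands
  expect_equal(signif_stars(c(0.0005, 0.005, 0.5, NA)),
               c("***", "**", "ns", ""))
})
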