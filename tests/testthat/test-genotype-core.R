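test_that("genotype normalization sorts pairs and propagates MISSING", {
  g <- normalize_genotype(c("T", "C", NA, "A"), c("C", "C", "A", NA))
  expect_equal(g$a1, c("C", "C", NA, NA))
  expect_equal(g$a2, c("T", "C", NA, NA))
  # heterozygote (a,b) equals (b,a)
  expect_identical(normalize_genotype("G", "A"), normalize_genotype("A", "G"))
  expect_error(normalize_genotype("X", "A"), "invalid allele")
})

test_that("cohort constructor enforces its invariants", {
  calls <- calls_from_wide(list(i1 = c(L1 = "CC"), i2 = c(L1 = "CT")))
  expect_s3_class(new_cohort(calls), "seb_cohort")
  dup <- dplyr::bind_rows(calls, calls[1, ])
  expect_error(new_cohort(dup), "duplicate individual x locus")
  expect_error(
    new_cohort(calls, groups = tibble::tibble(indiv = "ghost", group = "g")),
    "unknown individuals")
  bad_loci <- tibble::tibble(locus = "L1", contig = "c", pos = 0L,
                             ref = "C", alt = "T", qual = 1)
  expect_error(new_cohort(calls, bad_loci), "1-based")
})

test_that("read_vcf parses GT/DP, missing, phased and multi-allelic records", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path)
  ch <- read_vcf(path)
  expect_equal(dplyr::n_distinct(ch$calls$indiv), 3)
  expect_equal(nrow(ch$loci), 2)
  # GT 0/1 with DP 25 -> heterozygote ref/alt, depth 25
  s2l1 <- ch$calls[ch$calls$indiv == "s2" & ch$calls$locus == "L1", ]
  expect_equal(c(s2l1$a1, s2l1$a2), c("C", "T"))
  expect_equal(s2l1$depth, 25L)
  # "./." and half-call "./1" -> MISSING
  s3 <- ch$calls[ch$calls$indiv == "s3", ]
  expect_true(all(is.na(s3$a1)))
  # phased "0|0" treated as unphased homozygote
  s2l2 <- ch$calls[ch$calls$indiv == "s2" & ch$calls$locus == "L2", ]
  expect_equal(c(s2l2$a1, s2l2$a2), c("A", "A"))
  # multi-allelic 1/2 resolves against full ALT list
  s1l2 <- ch$calls[ch$calls$indiv == "s1" & ch$calls$locus == "L2", ]
  expect_equal(c(s1l2$a1, s1l2$a2), c("G", "T"))
  # QUAL and contig lengths captured
  expect_equal(ch$loci$qual, c(900, 750.5))
  expect_equal(attr(ch, "contig_lengths")[["ctg2"]], 15000)
  expect_error(read_vcf(path, sample_subset = "nope"), "not in VCF")
})

test_that("record accounting: records-in = loci-out + rejected", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path, add_indel = TRUE)
  ch <- read_vcf(path)
  expect_equal(nrow(ch$loci) + attr(ch, "n_rejected"), 3)
  expect_equal(attr(ch, "n_rejected"), 1)
})

test_that("GENEPOP writer emits Pop blocks and fixed allele coding", {
  ch <- fixed_two_group_cohort(n_per_group = 2, n_loci = 1)
  ch$calls$a1[1] <- NA
  ch$calls$a2[1] <- NA
  path <- withr::local_tempfile(fileext = ".gen")
  write_genepop(ch, path)
  lines <- readLines(path)
  expect_equal(sum(lines == "Pop"), 2)
  expect_true(any(grepl("0000", lines)))   # MISSING coding
  expect_true(any(grepl("0303", lines)))   # G = 03
})

test_that("genotype calls survive VCF -> cohort -> GENEPOP -> cohort", {
  sim <- simulate_cohort(sim_config(
    groups = c(a = 4, b = 4), n_diagnostic_per_pair = 2, n_shared = 5,
    missing_rate = 0.1, seed = 11))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  gen <- withr::local_tempfile(fileext = ".gen")
  write_cohort_vcf(sim$cohort, vcf)
  ch1 <- read_vcf(vcf)
  write_genepop(ch1, gen, groups = sim$cohort$groups)
  ch2 <- read_genepop(gen)
  key <- function(x) dplyr::arrange(
    cohort_calls(x)[c("indiv", "locus", "a1", "a2")], indiv, locus)
  expect_equal(key(ch2), key(sim$cohort))
})

test_that("genotype table reader handles both dialects and bad tokens", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("indiv,group,LOC1,LOC2",
               "ind1,mentella,CC,TT",
               "ind2,viviparus,CT,NN"), path)
  ch <- read_geno_table(path)
  expect_equal(ch$calls$a1[ch$calls$indiv == "ind1"], c("C", "T"))
  expect_equal(ch$calls$a2[ch$calls$indiv == "ind1"], c("C", "T"))
  expect_true(is.na(ch$calls$a1[ch$calls$indiv == "ind2" &
                                  ch$calls$locus == "LOC2"]))
  expect_equal(ch$groups$group, c("mentella", "viviparus"))

  # unparseable token -> MISSING, counted in a warning
  writeLines(c("indiv,group,LOC1", "ind1,m,CC", "ind2,m,Q?"), path)
  expect_warning(ch2 <- read_geno_table(path), "unparseable")
  expect_equal(attr(ch2, "n_bad_tokens"), 1L)

  # two-column-per-locus dialect
  writeLines(c("indiv,group,LOC1.1,LOC1.2", "ind1,m,C,T"), path)
  ch3 <- read_geno_table(path)
  expect_equal(c(ch3$calls$a1, ch3$calls$a2), c("C", "T"))

  writeLines(c("indiv,group,LOC1", "ind1,m,CC", "ind1,m,CT"), path)
  expect_error(read_geno_table(path), "duplicated individual")
  writeLines(c("indiv,group,LOC1", "ind1,m,CC,extra"), path)
  expect_error(read_geno_table(path), "ragged row")
})

test_that("CSV genotype table round-trips through write_geno_table", {
  ch <- fixed_two_group_cohort(n_per_group = 3, n_loci = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_geno_table(ch, path)
  back <- read_geno_table(path)
  key <- function(x) dplyr::arrange(
    cohort_calls(x)[c("indiv", "locus", "a1", "a2")], indiv, locus)
  expect_equal(key(back), key(ch))
})
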