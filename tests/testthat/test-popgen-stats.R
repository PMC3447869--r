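test_that("expected heterozygosity matches Nei's unbiased estimator", {
  expect_equal(expected_heterozygosity(c(A = 10)), 0)
  expect_equal(expected_heterozygosity(c(A = 1, B = 1)), 1)
  expect_equal(expected_heterozygosity(c(A = 72, B = 72)), 144 / 143 * 0.5)
  expect_error(expected_heterozygosity(c(A = 1)), "fewer than 2")
  # bounded in [0,1], zero iff monomorphic, for assorted count vectors
  set.seed(11)
  for (i in 1:25) {
    k <- sample(1:8, 1)
    counts <- sample(1:30, k, replace = TRUE)
    if (sum(counts) < 2) counts <- counts + 2L
    h <- expected_heterozygosity(counts)
    expect_gte(h, 0); expect_lte(h, 1)
    expect_identical(h == 0, k == 1L)
  }
})

test_that("allelic richness counts distinct alleles and ignores copy number", {
  expect_equal(allelic_richness(c(A = 3, B = 5)), 2)
  expect_error(allelic_richness(integer(0)), "no observed alleles")
  # a synthetic locus built to carry 8 alleles, as published for BM203
  prof <- allele_frequency_profile(list(BM203 = rep(1 / 8, 8)))
  gt <- sample_genotypes(prof, n = 400, seed = 3)
  expect_equal(allelic_richness(gt, "BM203"), 8)
  # duplicating every individual changes nothing
  dup <- genotype_table(rbind(gt$a1, gt$a1), rbind(gt$a2, gt$a2),
                        loci = gt$loci)
  expect_equal(allelic_richness(dup, "BM203"), allelic_richness(gt, "BM203"))
  expect_equal(expected_heterozygosity(dup, "BM203") == 0, FALSE)
})

test_that("observed heterozygosity is the fraction of heterozygous individuals", {
  hom <- gt_from_pairs(list(c(1L, 1L)), list(c(1L, 1L)), loci = "A")
  expect_equal(observed_heterozygosity(hom, "A"), 0)
  het <- gt_from_pairs(list(c(1L, 2L)), list(c(2L, 1L)), loci = "A")
  expect_equal(observed_heterozygosity(het, "A"), 1)
  mix <- gt_from_pairs(list(c(1L, 2L)), list(c(1L, 2L)), list(c(1L, 2L)),
                       list(c(2L, 2L)), loci = "A")
  expect_equal(observed_heterozygosity(mix, "A"), 0.75)
  miss <- gt_from_pairs(list(c(0L, 0L)), list(c(0L, 0L)), loci = "A")
  expect_error(observed_heterozygosity(miss, "A"), "no complete genotypes")
})

test_that("over-loci summaries reproduce the published means for both samples", {
  fin <- summarize_population(fin_tab)
  expect_equal(round(fin$mean_expected_het, 3), 0.692)
  expect_equal(round(fin$mean_allelic_richness, 2), 5.36)
  okl <- summarize_population(okl_tab)
  expect_equal(round(okl$mean_expected_het, 3), 0.742)
  expect_equal(round(okl$mean_allelic_richness, 2), 9.07)
  # permutation invariance over loci and the single-locus degenerate case
  shuf <- summarize_population(fin_tab[sample(nrow(fin_tab)), ])
  expect_equal(shuf$mean_expected_het, fin$mean_expected_het)
  one <- summarize_population(fin_tab[1, ])
  expect_equal(one$mean_expected_het, fin_tab$expected_het[1])
  expect_error(summarize_population(fin_tab[0, ]), "at least one locus")
})

test_that("Mann-Whitney Z is tie-corrected, antisymmetric, and matches wilcox.test", {
  same <- mann_whitney_one_tailed(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$Z, 0)
  expect_equal(same$p_one_tailed, 0.5)
  a <- mann_whitney_one_tailed(fin_tab$allele_count, okl_tab$allele_count)
  b <- mann_whitney_one_tailed(okl_tab$allele_count, fin_tab$allele_count)
  expect_equal(a$Z, -b$Z)
  ref <- stats::wilcox.test(fin_tab$allele_count, okl_tab$allele_count,
                            alternative = "less", exact = FALSE,
                            correct = FALSE)
  expect_equal(a$p_one_tailed, ref$p.value, tolerance = 1e-10)
  expect_error(mann_whitney_one_tailed(numeric(0), 1), "non-empty")
})

test_that("asymptotic one-tailed p stays within 0.05 of the exact permutation p", {
  set.seed(21)
  for (i in 1:20) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(seq_len(50), n1)   # distinct values: no ties
    y <- sample(setdiff(seq_len(50), x), n2)
    got <- mann_whitney_one_tailed(x, y)$p_one_tailed
    expect_lt(abs(got - exact_mw_p(x, y)), 0.05)
  }
})

test_that("complete-case subsampling is uniform, reproducible, and size-checked", {
  prof <- allele_frequency_profile(list(A = c(0.5, 0.5), B = c(0.3, 0.7)))
  gt <- sample_genotypes(prof, n = 40, missing_rate = 0.15, seed = 5)
  cc <- sum(rowSums(gt$a1 == 0L | gt$a2 == 0L) == 0L)
  s1 <- subsample_complete_cases(gt, 10, seed = 9)
  s2 <- subsample_complete_cases(gt, 10, seed = 9)
  expect_identical(s1$a1, s2$a1)
  expect_equal(nrow(s1$a1), 10)
  expect_true(all(s1$a1 > 0L & s1$a2 > 0L))
  # n equal to the number of complete cases returns them all (any order)
  all_cc <- subsample_complete_cases(gt, cc, seed = 1)
  expect_equal(nrow(all_cc$a1), cc)
  expect_setequal(rowSums(all_cc$a1 * 7L + all_cc$a2),
                  rowSums(gt$a1 * 7L + gt$a2)[rowSums(gt$a1 == 0L | gt$a2 == 0L) == 0L])
  expect_equal(nrow(subsample_complete_cases(gt, 0)$a1), 0)
  expect_error(subsample_complete_cases(gt, nrow(gt$a1) + 1), "complete cases")
})
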