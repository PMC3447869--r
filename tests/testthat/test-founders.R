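test_that("minimal founder heterozygosity is max(0, k - n) heterozygotes per locus", {
  expect_equal(min_founder_heterozygosity(fin_tab$allele_count, 4), 22 / 56)
  expect_equal(round(min_founder_heterozygosity(fin_tab$allele_count, 4), 2), 0.39)
  expect_equal(min_founder_heterozygosity(c(2, 3, 4), 4), 0)
  expect_equal(min_founder_heterozygosity(8, 4), 1)
  expect_error(min_founder_heterozygosity(9, 4), "2 \\* n_founders")
})

test_that("the analytic minimum agrees with exhaustive allele assignment", {
  for (n in 2:3) for (k in seq_len(2 * n)) {
    expect_equal(min_founder_heterozygosity(k, n),
                 brute_min_het_founders(k, n) / n,
                 info = sprintf("k=%d n=%d", k, n))
  }
})

test_that("founder construction meets every scheme's constraints exactly", {
  ar <- finland_allelic_richness()
  for (scheme in c("max_het", "min_het", "max_ar")) {
    spec <- founder_spec(scheme = scheme)
    pop <- build_founders(spec)
    expect_equal(sum(pop$female), 3)
    expect_equal(sum(!pop$female), 1)
    per_locus_ar <- vapply(seq_along(spec$loci), function(j)
      length(unique(c(pop$a1[, j], pop$a2[, j]))), 0)
    expect_equal(per_locus_ar, unname(spec$ar_per_locus))
    het <- pop$a1 != pop$a2
    if (scheme %in% c("max_het", "max_ar")) {
      expect_true(all(het))
    } else {
      expect_equal(unname(colSums(het)), unname(pmax(0L, ar - 4L)))
      expect_equal(population_H(pop),
                   min_founder_heterozygosity(ar, 4))
    }
  }
})

test_that("maximal-richness founders carry each allele exactly once", {
  pop <- build_founders(founder_spec(scheme = "max_ar"))
  for (j in seq_len(ncol(pop$a1))) {
    counts <- table(c(pop$a1[, j], pop$a2[, j]))
    expect_equal(length(counts), 8L)
    expect_true(all(counts == 1L))
  }
  expect_equal(population_AR(pop), 8)
  expect_equal(population_H(pop), 1)
})

test_that("degenerate founder specs are rejected or handled", {
  expect_error(founder_spec(ar_per_locus = c(1, 2), scheme = "max_het"),
               "monomorphic")
  expect_error(founder_spec(ar_per_locus = 9), "between 1 and")
  # min_het with k = 2 and 4 founders: two homozygous classes, no heterozygote
  pop <- build_founders(founder_spec(ar_per_locus = 2, scheme = "min_het"))
  expect_equal(sum(pop$a1 != pop$a2), 0)
  expect_equal(sort(unique(c(pop$a1, pop$a2))), 1:2)
  # max_het with k = 2: every founder carries the (1,2) pair
  pop <- build_founders(founder_spec(ar_per_locus = 2, scheme = "max_het"))
  expect_true(all(pop$a1 != pop$a2))
  expect_true(all((pop$a1 == 1L & pop$a2 == 2L) | (pop$a1 == 2L & pop$a2 == 1L)))
})

test_that("second-introduction cohorts are heterozygous with disjoint novel alleles", {
  ev <- introduction_event()
  existing <- c(1L, 5L, 17L)
  cohort <- build_introduction_cohort(ev, paste0("L", 1:14), existing)
  expect_equal(length(cohort$age), 4)
  expect_equal(sum(cohort$female), 3)
  expect_true(all(cohort$age == 1L))
  expect_true(all(cohort$a1 != cohort$a2))
  for (j in 1:14) {
    alleles <- c(cohort$a1[, j], cohort$a2[, j])
    expect_equal(length(unique(alleles)), 8)
    expect_length(intersect(alleles, existing), 0)
  }
  empty <- build_introduction_cohort(introduction_event(n_females = 0, n_males = 0),
                                     paste0("L", 1:3), existing)
  expect_equal(length(empty$age), 0)
})
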