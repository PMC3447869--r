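two_parent_pop <- function(ma, pa) {
  new_deer_pop(a1 = rbind(ma[1], pa[1]), a2 = rbind(ma[2], pa[2]),
               female = c(TRUE, FALSE), age = c(2L, 2L))
}

test_that("transmission is Mendelian: uniform over parental allele pairs", {
  set.seed(31)
  # AA x AA is deterministic
  pop <- two_parent_pop(c(1L, 1L), c(1L, 1L))
  off <- transmit(pop, rep(1L, 50), rep(2L, 50))
  expect_true(all(off$a1 == 1L & off$a2 == 1L))
  # AB x CD: four offspring classes, each with probability 1/4
  pop <- two_parent_pop(c(1L, 2L), c(3L, 4L))
  off <- transmit(pop, rep(1L, 10000), rep(2L, 10000))
  expect_true(all(off$a1 %in% 1:2 & off$a2 %in% 3:4))
  counts <- table(paste(off$a1, off$a2))
  expect_equal(length(counts), 4L)
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("offspring alleles never leave the parental pool across loci", {
  set.seed(32)
  founders <- build_founders(founder_spec(scheme = "max_het"))
  off <- transmit(founders, sample(1:3, 40, TRUE), rep(4L, 40))
  for (j in seq_len(ncol(founders$a1))) {
    pool <- unique(c(founders$a1[, j], founders$a2[, j]))
    expect_true(all(off$a1[, j] %in% pool) && all(off$a2[, j] %in% pool))
  }
})

test_that("population heterozygosity and richness behave on simple populations", {
  pop <- build_founders(founder_spec(scheme = "max_ar"))
  expect_equal(individual_heterozygosity(pop), rep(1, 4))
  expect_equal(population_H(pop), 1)
  half <- new_deer_pop(a1 = rbind(rep(1L, 14), rep(1L, 14)),
                       a2 = rbind(rep(1L, 14), rep(2L, 14)),
                       female = c(TRUE, FALSE), age = c(1L, 1L))
  expect_equal(population_H(half), 0.5)
  expect_equal(population_AR(pop_subset(half, 1)), 1)
  # duplication invariance
  expect_equal(population_H(pop_bind(half, half)), population_H(half))
  empty <- pop_subset(half, integer(0))
  expect_error(population_H(empty), "extinct")
  expect_error(population_AR(empty), "extinct")
})

test_that("the scripted establishment follows the historical record", {
  cfg <- scenario_config("A1", n_replicates = 1)
  founders <- build_founders(cfg$founder)
  set.seed(33)
  est <- scripted_establishment(founders, cfg)
  expect_equal(est$trajectory, c(4, 4, 4, 6, 8))
  expect_equal(length(est$pop$age), 8)
  # founders aged 4; 1937 fawns aged 1; 1938 fawns aged 0; no deaths
  expect_equal(sort(est$pop$age), c(0L, 0L, 1L, 1L, 4L, 4L, 4L, 4L))
  # every fawn sired by the single founder male, borne by the two dams
  sire_id <- est$pop$id[which(!founders$female)[1]]
  fawns <- which(est$pop$age < 4L)
  expect_true(all(est$pop$father[fawns] == sire_id))
  expect_setequal(unique(est$pop$mother[fawns]), est$pop$id[1:2])
  # 1937 calf sexes follow the configured values
  expect_equal(sum(est$pop$female[est$pop$age == 1L]), 1)
  # fawn alleles are a subset of the founder pool, locus by locus
  for (j in c(1L, 7L)) {
    pool <- unique(c(founders$a1[, j], founders$a2[, j]))
    expect_true(all(est$pop$a1[fawns, j] %in% pool))
  }
  bad <- founders
  bad$female <- rep(TRUE, 4)
  expect_error(scripted_establishment(bad, cfg), "3 female")
  cfg4 <- cfg; cfg4$horizon <- 4L
  expect_error(scripted_establishment(founders, cfg4), "horizon")
})

test_that("the annual step obeys its demographic limits", {
  set.seed(34)
  base <- build_founders(founder_spec(scheme = "max_het"))
  base$age <- rep(3L, 4)
  # no reproduction, certain survival: constant until the lifespan cap culls
  vr_static <- vital_rates(1, 1, 1, max_age = 16L,
                           fecundity = rbind(c(1, 0, 0), matrix(rep(c(1, 0, 0), 16),
                                                                ncol = 3, byrow = TRUE)))
  pop <- base
  for (t in 1:13) pop <- annual_step(pop, vr_static)$pop
  expect_equal(length(pop$age), 4)      # ages 16: still alive
  pop <- annual_step(pop, vr_static)$pop
  expect_equal(length(pop$age), 0)      # past the cap: all die
  # zero survival: extinction in one step
  vr_dead <- vital_rates(0, 0, 0)
  expect_equal(length(annual_step(base, vr_dead)$pop$age), 0)
})

test_that("realised fecundity matches the schedule's moments", {
  set.seed(35)
  n_f <- 4000L
  pop <- new_deer_pop(a1 = matrix(1L, n_f + 50L, 1), a2 = matrix(2L, n_f + 50L, 1),
                      female = rep(c(TRUE, FALSE), c(n_f, 50L)),
                      age = rep(3L, n_f + 50L))
  vr <- vital_rates(1, 1, 1, max_age = 30L, fecundity = default_fecundity(30L))
  out <- annual_step(pop, vr)$pop
  births <- length(out$age) - (n_f + 50L)
  p <- default_fecundity()["2", ]
  mu <- p[["p1"]] + 2 * p[["p2"]]
  sigma2 <- p[["p1"]] + 4 * p[["p2"]] - mu^2
  expect_lt(abs(births - n_f * mu), 3 * sqrt(n_f * sigma2))
})

test_that("with certain survival the population follows the birth recurrence", {
  set.seed(36)
  # exactly one fawn per breeding female, no deaths below the age cap
  fec <- rbind(c(1, 0, 0), matrix(rep(c(0, 1, 0), 40), ncol = 3, byrow = TRUE))
  vr <- vital_rates(1, 1, 1, max_age = 40L, fecundity = fec)
  pop <- new_deer_pop(a1 = matrix(1L, 6, 2), a2 = matrix(2L, 6, 2),
                      female = rep(c(TRUE, FALSE), 3), age = rep(1L, 6))
  for (t in 1:10) {
    expected <- length(pop$age) + sum(pop$female & pop$age >= 1L)
    pop <- annual_step(pop, vr)$pop
    expect_equal(length(pop$age), expected)
  }
})

test_that("allelic closure holds and drift only loses alleles between introductions", {
  cfg <- scenario_config("A1", n_replicates = 1, horizon = 16L)
  set.seed(37)
  founders <- build_founders(cfg$founder)
  pool <- lapply(seq_len(ncol(founders$a1)), function(j)
    unique(c(founders$a1[, j], founders$a2[, j])))
  pop <- scripted_establishment(founders, cfg)$pop
  ar_prev <- population_AR(pop)
  for (t in 5:16) {
    pop <- annual_step(pop, cfg$vital)$pop
    if (length(pop$age) == 0) break
    for (j in c(1L, 6L, 14L))
      expect_true(all(c(pop$a1[, j], pop$a2[, j]) %in% pool[[j]]))
    ar_now <- population_AR(pop)
    expect_lte(ar_now, ar_prev + 1e-12)
    ar_prev <- ar_now
  }
})

test_that("replicates are reproducible and scenario summaries are well formed", {
  cfg <- scenario_config("C", n_replicates = 1, horizon = 18L)
  r1 <- run_replicate(cfg, seed = 42)
  r2 <- run_replicate(cfg, seed = 42)
  expect_identical(r1, r2)
  expect_equal(r1$trajectory[1:5], c(4, 4, 4, 6, 8))
  # horizon 5: the scripted population runs one stochastic year only
  cfg5 <- scenario_config("A1", n_replicates = 3, horizon = 5L)
  sim <- run_scenario(cfg5)
  expect_equal(nrow(sim$trajectory), 6)
  one <- run_scenario(scenario_config("A1", n_replicates = 1, horizon = 8L,
                                      seed = 7))
  if (!one$replicates$extinct[1]) {
    expect_equal(one$summary[["H_p2.5"]], one$summary[["mean_H"]])
    expect_equal(one$summary[["H_p97.5"]], one$summary[["mean_H"]])
  }
})

test_that("more founder or introduced alleles yield more retained richness", {
  simA <- cached_scenario("A1")
  simC <- cached_scenario("C")
  simB <- cached_scenario("B")
  # 8 founder alleles per locus retain more than the observed 5.36
  expect_gt(simB$summary[["mean_AR"]], simA$summary[["mean_AR"]])
  # a successful novel-allele introduction can only add richness
  expect_gt(simC$summary[["mean_AR"]], simA$summary[["mean_AR"]])
  expect_gt(simB$summary[["mean_H"]], simA$summary[["mean_H"]])
})
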