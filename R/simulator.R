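# ---- population container ---------------------------------------------
# A simulated population is a plain list of parallel vectors/matrices:
#   a1, a2  integer allele matrices (individuals x loci)
#   female  logical; age integer years; id, mother, father integer ids.
# Kept deliberately light: the annual step touches every element.

new_deer_pop <- function(a1, a2, female, age,
                         id = seq_len(nrow(a1)),
                         mother = rep(NA_integer_, nrow(a1)),
                         father = rep(NA_integer_, nrow(a1))) {
  structure(list(a1 = a1, a2 = a2, female = female, age = as.integer(age),
                 id = as.integer(id), mother = as.integer(mother),
                 father = as.integer(father)),
            class = "deer_pop")
}

#' @export
print.deer_pop <- function(x, ...) {
  cat(sprintf("deer_pop: %d individuals (%d F / %d M), %d loci, ages %s\n",
              length(x$age), sum(x$female), sum(!x$female), ncol(x$a1),
              if (length(x$age)) paste(range(x$age), collapse = "-") else "-"))
  invisible(x)
}

pop_size <- function(pop) length(pop$age)

pop_bind <- function(pop, extra) {
  new_deer_pop(rbind(pop$a1, extra$a1), rbind(pop$a2, extra$a2),
               c(pop$female, extra$female), c(pop$age, extra$age),
               id = c(pop$id, extra$id),
               mother = c(pop$mother, extra$mother),
               father = c(pop$father, extra$father))
}

pop_subset <- function(pop, keep) {
  new_deer_pop(pop$a1[keep, , drop = FALSE], pop$a2[keep, , drop = FALSE],
               pop$female[keep], pop$age[keep], id = pop$id[keep],
               mother = pop$mother[keep], father = pop$father[keep])
}

#' Convert a simulated population to a genotype table
#'
#' Bridges the simulator's internal population state to the empirical
#' statistics functions ([diversity_summary()] etc.).
#'
#' @param pop a `deer_pop`.
#' @param population label for the resulting table.
#' @return A [genotype_table()].
#' @export
as_genotype_table <- function(pop, population = "simulated") {
  stopifnot(inherits(pop, "deer_pop"))
  genotype_table(pop$a1, pop$a2, loci = colnames(pop$a1),
                 population = population)
}

# ---- Mendelian transmission -------------------------------------------

#' Mendelian transmission of multi-locus genotypes
#'
#' Each offspring receives, independently at every locus, one uniformly
#' chosen allele from its mother and one from its father.  Vectorised over
#' offspring: `mothers` and `fathers` are row indices into the population's
#' allele matrices, one entry per fawn.
#'
#' @param pop a `deer_pop` holding the parents.
#' @param mothers,fathers integer row indices of equal length.
#' @return List of two integer matrices `a1` (maternal copies) and `a2`
#'   (paternal copies), one row per offspring.
#' @export
transmit <- function(pop, mothers, fathers) {
  stopifnot(length(mothers) == length(fathers))
  L <- ncol(pop$a1)
  nf <- length(mothers)
  ma <- pop$a1[mothers, , drop = FALSE]
  swap <- matrix(runif(nf * L) < 0.5, nf, L)
  ma[swap] <- pop$a2[mothers, , drop = FALSE][swap]
  pa <- pop$a1[fathers, , drop = FALSE]
  swap <- matrix(runif(nf * L) < 0.5, nf, L)
  pa[swap] <- pop$a2[fathers, , drop = FALSE][swap]
  list(a1 = ma, a2 = pa)
}

# ---- diversity of the living population -------------------------------

#' Heterozygosity and allelic richness of a simulated population
#'
#' `individual_heterozygosity()` is the proportion of an individual's loci
#' carrying two distinct alleles; `population_H()` averages it over the
#' living individuals; `population_AR()` is the mean over loci of the
#' number of distinct alleles present in the living population.
#'
#' @param pop a `deer_pop`.
#' @return `individual_heterozygosity()`: numeric vector, one value per
#'   individual; `population_H()`, `population_AR()`: single numbers.
#' @export
individual_heterozygosity <- function(pop) {
  stopifnot(ncol(pop$a1) >= 1)
  rowMeans(pop$a1 != pop$a2)
}

#' @rdname individual_heterozygosity
#' @export
population_H <- function(pop) {
  if (pop_size(pop) == 0) stop("population is extinct: heterozygosity undefined")
  mean(individual_heterozygosity(pop))
}

#' @rdname individual_heterozygosity
#' @export
population_AR <- function(pop) {
  if (pop_size(pop) == 0) stop("population is extinct: allelic richness undefined")
  mean(vapply(seq_len(ncol(pop$a1)),
              function(j) length(unique(c(pop$a1[, j], pop$a2[, j]))), 0))
}

# ---- vital rates and configuration ------------------------------------

#' Default age-specific fawn-number probabilities
#'
#' Probabilities of a female producing 0, 1 or 2 fawns in a year, by age.
#' Age 0 never reproduces; yearlings use a modest schedule; adults use a
#' schedule whose mean (1.13 fawns) was calibrated by least squares so the
#' deterministic expected trajectory tracks the census record of the
#' establishment years (12 animals in 1939 up to roughly 200 by 1956).
#'
#' @param max_age oldest age class carried in the schedule.
#' @return Numeric matrix with rows `0:max_age` and columns `p0`, `p1`, `p2`.
#' @export
default_fecundity <- function(max_age = 16L) {
  sched <- rbind(c(1, 0, 0),                 # fawns do not reproduce
                 c(0.6, 0.3, 0.1),           # yearlings: mean 0.5
                 matrix(rep(c(0.235, 0.4, 0.365), max_age - 1),
                        ncol = 3, byrow = TRUE))  # adults: mean 1.13
  dimnames(sched) <- list(0:max_age, c("p0", "p1", "p2"))
  sched
}

#' Demographic vital rates
#'
#' Over-winter survival by age class, maximum lifespan, and the fecundity
#' schedule.  Defaults are the white-tailed deer values used throughout:
#' newborn 0.75, yearling 0.80, adult 0.85, lifespan cap 16 years.
#'
#' @param survival_newborn,survival_yearling,survival_adult over-winter
#'   survival probabilities for an animal in its first, second, and later
#'   winters.
#' @param max_age maximum attainable age in years; death is certain at the
#'   transition past it.
#' @param fecundity matrix as produced by [default_fecundity()]: rows are
#'   ages starting at 0, columns the probabilities of 0/1/2 fawns (each row
#'   must sum to 1).
#' @param male_min_age youngest age at which a male can sire.
#' @return An object of class `vital_rates`.
#' @export
vital_rates <- function(survival_newborn = 0.75, survival_yearling = 0.80,
                        survival_adult = 0.85, max_age = 16L,
                        fecundity = default_fecundity(max_age),
                        male_min_age = 1L) {
  s <- c(survival_newborn, survival_yearling, survival_adult)
  stopifnot(all(s >= 0 & s <= 1), max_age >= 1,
            ncol(fecundity) == 3, nrow(fecundity) >= 2,
            all(fecundity >= 0),
            all(abs(rowSums(fecundity) - 1) < 1e-9))
  structure(list(survival_newborn = survival_newborn,
                 survival_yearling = survival_yearling,
                 survival_adult = survival_adult,
                 max_age = as.integer(max_age),
                 fecundity = fecundity,
                 male_min_age = as.integer(male_min_age)),
            class = "vital_rates")
}

#' Founding-scenario configuration
#'
#' Bundles everything one simulated introduction needs.  The named
#' scenarios are:
#' * `"A1"` — founders carry the observed per-locus allele counts, maximal
#'   heterozygosity (founder H = 1);
#' * `"A2"` — same allele counts, minimal heterozygosity (H = 0.39);
#' * `"B"`  — maximal allelic richness (8 alleles per locus, H = 1);
#' * `"C"`  — as A1 plus a successful second introduction (1 male, 3
#'   females, fully heterozygous with all-novel alleles) at step 15.
#'
#' @param scheme scenario label, or `"custom"` to supply `founders`
#'   yourself.
#' @param founder a [founder_spec()]; defaults follow `scheme`.
#' @param vital a [vital_rates()].
#' @param horizon number of annual time steps (default 45, i.e. 1934-1979).
#' @param n_replicates number of replicate introductions (default 1000).
#' @param seed base integer seed; replicate `i` uses `seed + i`.
#' @param second_introduction an [introduction_event()] or `NULL`; filled
#'   in automatically for scheme `"C"`.
#' @param calf_sexes_1937 sexes of the two scripted 1937 calves (recorded
#'   as known but unpublished); default one female, one male.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(scheme = c("A1", "A2", "B", "C", "custom"),
                            founder = NULL,
                            vital = vital_rates(),
                            horizon = 45L, n_replicates = 1000L, seed = 1L,
                            second_introduction = NULL,
                            calf_sexes_1937 = c("female", "male")) {
  scheme <- match.arg(scheme)
  if (is.null(founder))
    founder <- switch(scheme,
                      A1 = founder_spec(scheme = "max_het"),
                      A2 = founder_spec(scheme = "min_het"),
                      B  = founder_spec(scheme = "max_ar"),
                      C  = founder_spec(scheme = "max_het"),
                      stop("scheme 'custom' requires an explicit founder spec"))
  if (scheme == "C" && is.null(second_introduction))
    second_introduction <- introduction_event()
  stopifnot(inherits(founder, "founder_spec"), inherits(vital, "vital_rates"),
            horizon >= 5, n_replicates >= 1,
            all(calf_sexes_1937 %in% c("female", "male")),
            length(calf_sexes_1937) == 2)
  structure(list(scheme = scheme, founder = founder, vital = vital,
                 horizon = as.integer(horizon),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 second_introduction = second_introduction,
                 calf_sexes_1937 = calf_sexes_1937),
            class = "scenario_config")
}

# ---- the scripted establishment years ---------------------------------

#' Scripted establishment, 1934-1938 (steps 0-4)
#'
#' The first five years follow the historical record deterministically: the
#' four founders (three females, one male, released as calves) all survive;
#' in 1937 (step 3) two designated females each bear one fawn sired by the
#' single male; in 1938 (step 4) the same two females again bear one fawn
#' each.  The population therefore numbers 4, 4, 4, 6, 8 at the ends of
#' steps 0-4.  Fawn genotypes are drawn by [transmit()]; 1938 fawn sexes
#' are random (unrecorded), 1937 sexes follow `config$calf_sexes_1937`.
#'
#' @param founders a `deer_pop` of 3 females + 1 male aged 0, e.g. from
#'   [build_founders()].
#' @param config a [scenario_config()].
#' @return List with the population at the end of step 4 (`pop`) and the
#'   size trajectory for steps 0-4 (`trajectory`).
#' @export
scripted_establishment <- function(founders, config) {
  stopifnot(inherits(founders, "deer_pop"))
  if (config$horizon < 5) stop("horizon must cover the scripted steps 0-4")
  if (sum(founders$female) != 3 || sum(!founders$female) != 1 ||
      any(founders$age != 0))
    stop("the scripted establishment expects 3 female + 1 male founders aged 0")
  pop <- founders
  dams <- which(pop$female)[1:2]
  sire <- which(!pop$female)[1]
  next_id <- max(pop$id) + 1L
  born <- function(pop, sexes, ids) {
    g <- transmit(pop, dams, c(sire, sire))
    pop_bind(pop, new_deer_pop(g$a1, g$a2, female = sexes, age = c(0L, 0L),
                               id = ids, mother = pop$id[dams],
                               father = rep(pop$id[sire], 2)))
  }
  pop$age <- pop$age + 3L                      # steps 1-3 begin; no deaths
  pop <- born(pop, config$calf_sexes_1937 == "female", next_id + 0:1)
  pop$age <- pop$age + 1L                      # step 4
  pop <- born(pop, runif(2) < 0.5, next_id + 2:3)
  list(pop = pop, trajectory = c(4, 4, 4, 6, 8))
}

# ---- one stochastic year ----------------------------------------------

#' Advance the population by one stochastic year
#'
#' Event order within a year: (1) every female of breeding age is paired
#' with one male drawn uniformly with replacement from the eligible males
#' and bears 0/1/2 fawns per the age-specific fecundity schedule, each fawn
#' female with probability 0.5 and its genotype drawn by [transmit()];
#' (2) all animals age one year; (3) over-winter survival is Bernoulli per
#' age class, so this year's fawns face the newborn rate in their first
#' winter; (4) animals beyond the lifespan cap die.  If either sex is
#' absent no fawns are produced.
#'
#' @param pop a `deer_pop`.
#' @param vital a [vital_rates()].
#' @param next_id first unused individual id.
#' @return List with the surviving population (`pop`) and the updated
#'   `next_id`.
#' @export
annual_step <- function(pop, vital, next_id = max(0L, pop$id) + 1L) {
  fec <- vital$fecundity
  mo <- which(pop$female & pop$age >= 1L)
  fa <- which(!pop$female & pop$age >= vital$male_min_age)
  if (length(mo) && length(fa)) {
    arow <- pmin(pop$age[mo], nrow(fec) - 1L) + 1L
    u <- runif(length(mo))
    nf <- (u > fec[arow, 1]) + (u > fec[arow, 1] + fec[arow, 2])
    dams <- rep(mo, nf)
    nb <- length(dams)
    if (nb) {
      sires <- fa[sample.int(length(fa), nb, replace = TRUE)]
      g <- transmit(pop, dams, sires)
      fawns <- new_deer_pop(g$a1, g$a2, female = runif(nb) < 0.5,
                            age = rep(0L, nb), id = next_id + seq_len(nb) - 1L,
                            mother = pop$id[dams], father = pop$id[sires])
      next_id <- next_id + nb
      pop <- pop_bind(pop, fawns)
    }
  }
  pop$age <- pop$age + 1L
  s <- ifelse(pop$age == 1L, vital$survival_newborn,
              ifelse(pop$age == 2L, vital$survival_yearling,
                     vital$survival_adult))
  keep <- runif(length(s)) < s & pop$age <= vital$max_age
  list(pop = pop_subset(pop, keep), next_id = next_id)
}

# ---- replicates and scenario summaries --------------------------------

#' Run one replicate introduction
#'
#' Executes the scripted establishment and then [annual_step()] through the
#' horizon, inserting the second-introduction cohort at its scheduled step
#' when configured.  Fully reproducible: the same `seed` yields an
#' identical result.  A replicate is flagged extinct when no animals
#' remain, or when either sex is absent at the horizon (reproduction has
#' then ceased for good).
#'
#' @param config a [scenario_config()].
#' @param seed integer seed for this replicate.
#' @return List with `trajectory` (population size at the end of steps
#'   `0:horizon`), `final_H`, `final_AR`, `final_N` and `extinct`.
#' @export
run_replicate <- function(config, seed) {
  set.seed(seed)
  founders <- build_founders(config$founder)
  est <- scripted_establishment(founders, config)
  pop <- est$pop
  traj <- c(est$trajectory, rep(NA_real_, config$horizon - 4L))
  next_id <- max(pop$id) + 1L
  intro <- config$second_introduction
  for (t in 5:config$horizon) {
    if (!is.null(intro) && intro$time_step == t) {
      cohort <- build_introduction_cohort(intro, colnames(pop$a1),
                                          c(pop$a1, pop$a2,
                                            config$founder$ar_per_locus))
      cohort$id <- next_id + seq_len(pop_size(cohort)) - 1L
      next_id <- next_id + pop_size(cohort)
      pop <- pop_bind(pop, cohort)
    }
    st <- annual_step(pop, config$vital, next_id)
    pop <- st$pop; next_id <- st$next_id
    traj[t + 1L] <- pop_size(pop)
    if (pop_size(pop) == 0L &&
        (is.null(intro) || intro$time_step <= t)) {
      traj[(t + 1L):(config$horizon + 1L)] <- 0
      break
    }
  }
  extinct <- pop_size(pop) == 0L || sum(pop$female) == 0L ||
    sum(!pop$female) == 0L
  list(trajectory = traj,
       final_H = if (pop_size(pop)) population_H(pop) else NA_real_,
       final_AR = if (pop_size(pop)) population_AR(pop) else NA_real_,
       final_N = pop_size(pop),
       extinct = extinct)
}

#' Simulate a founding scenario
#'
#' The package's main entry point: runs `n_replicates` independent
#' replicate introductions under one [scenario_config()] and aggregates the
#' non-extinct replicates into means and empirical 2.5/97.5 percentiles of
#' final heterozygosity, final allelic richness, and the per-step
#' population-size trajectory.
#'
#' @param config a [scenario_config()]; alternatively a scheme label
#'   (`"A1"`, `"A2"`, `"B"`, `"C"`), in which case the remaining arguments
#'   are passed to [scenario_config()].
#' @param ... passed to [scenario_config()] when `config` is a label.
#' @return An object of class `deer_sim`: a list with `summary` (named
#'   vector of means and percentiles), `replicates` (data frame, one row
#'   per replicate), `trajectory` (data frame of mean and percentile bands
#'   per step), `n_extinct`, and `config`.
#' @examples
#' sim <- run_scenario("A1", n_replicates = 20, seed = 42)
#' sim
#' @export
run_scenario <- function(config, ...) {
  if (is.character(config)) config <- scenario_config(config, ...)
  stopifnot(inherits(config, "scenario_config"))
  reps <- lapply(seq_len(config$n_replicates),
                 function(i) run_replicate(config, config$seed + i))
  df <- data.frame(replicate = seq_along(reps),
                   final_H = vapply(reps, `[[`, 0, "final_H"),
                   final_AR = vapply(reps, `[[`, 0, "final_AR"),
                   final_N = vapply(reps, `[[`, 0, "final_N"),
                   extinct = vapply(reps, `[[`, TRUE, "extinct"))
  ok <- !df$extinct
  if (!any(ok)) stop("all replicates went extinct; nothing to summarise")
  q <- function(x, p) unname(quantile(x, p, na.rm = TRUE, type = 7))
  tr <- do.call(rbind, lapply(reps[ok], `[[`, "trajectory"))
  trajectory <- data.frame(step = 0:config$horizon,
                           mean_N = colMeans(tr),
                           N_p2.5 = apply(tr, 2, q, 0.025),
                           N_p97.5 = apply(tr, 2, q, 0.975))
  summary <- c(mean_H = mean(df$final_H[ok]),
               H_p2.5 = q(df$final_H[ok], 0.025),
               H_p97.5 = q(df$final_H[ok], 0.975),
               mean_AR = mean(df$final_AR[ok]),
               AR_p2.5 = q(df$final_AR[ok], 0.025),
               AR_p97.5 = q(df$final_AR[ok], 0.975))
  structure(list(summary = summary, replicates = df, trajectory = trajectory,
                 n_extinct = sum(!ok), config = config),
            class = "deer_sim")
}

#' @export
print.deer_sim <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Scenario %s: %d replicates (%d extinct, excluded)\n",
              x$config$scheme, x$config$n_replicates, x$n_extinct))
  cat(sprintf("  final H  = %.3f (%.3f-%.3f)\n", s["mean_H"], s["H_p2.5"],
              s["H_p97.5"]))
  cat(sprintf("  final AR = %.2f (%.2f-%.2f)\n", s["mean_AR"], s["AR_p2.5"],
              s["AR_p97.5"]))
  cat(sprintf("  final N: mean %.0f after %d steps\n",
              mean(x$replicates$final_N[!x$replicates$extinct]),
              x$config$horizon))
  invisible(x)
}

#' @export
summary.deer_sim <- function(object, ...) {
  out <- c(object$summary, n_extinct = object$n_extinct,
           n_replicates = object$config$n_replicates)
  class(out) <- "summary.deer_sim"
  out
}

#' @export
print.summary.deer_sim <- function(x, ...) {
  print(unclass(round(x, 4)))
  invisible(x)
}

#' Plot the simulated population trajectory
#'
#' Mean population size per step with the 2.5/97.5 percentile band, on a
#' log10 axis, optionally overlaying the historical census record.
#'
#' @param x a `deer_sim`.
#' @param census optional data frame with columns `step` and `N` to overlay
#'   (see [census_anchors()]).
#' @param ... passed to [graphics::plot()].
#' @export
plot.deer_sim <- function(x, census = census_anchors(), ...) {
  tr <- x$trajectory
  pos <- tr$mean_N > 0
  graphics::plot(tr$step[pos], log10(tr$mean_N[pos]), type = "l", lwd = 2,
                 xlab = "years since introduction",
                 ylab = "log10 population size", ...)
  graphics::lines(tr$step, log10(pmax(tr$N_p2.5, 1e-3)), lty = 3)
  graphics::lines(tr$step, log10(pmax(tr$N_p97.5, 1e-3)), lty = 3)
  if (!is.null(census))
    graphics::points(census$step, log10(census$N), pch = 16)
  invisible(x)
}

#' Census record of the establishment years
#'
#' Published population-size estimates for the Finnish white-tailed deer,
#' expressed in years since the 1934 introduction.  Ranges are represented
#' by their midpoints.  The 1961 figure (~1000) is retained for plotting
#' but was judged unreliable in the source and is excluded from the
#' fecundity calibration.
#'
#' @return Data frame with columns `step`, `year`, `N` and `reliable`.
#' @export
census_anchors <- function() {
  data.frame(step = c(0, 3, 4, 5, 7, 11, 14, 22, 27),
             year = c(1934, 1937, 1938, 1939, 1941, 1945, 1948, 1956, 1961),
             N = c(5, 6, 8, 12, 17.5, 35, 95, 200, 1000),
             reliable = c(rep(TRUE, 8), FALSE))
}
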