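#' Founder genotype specification
#'
#' Describes how the founding individuals' multi-locus genotypes are
#' constructed.  Three schemes are supported, mirroring the founding
#' scenarios explored for the Finnish white-tailed deer introduction:
#'
#' * `"max_het"` — every founder heterozygous at every locus while the
#'   locus displays exactly `ar_per_locus` distinct alleles (scenario A1);
#' * `"min_het"` — the minimal attainable number of heterozygous founders
#'   per locus given `ar_per_locus` distinct alleles (scenario A2);
#' * `"max_ar"` — all `2 * n` gene copies distinct, i.e. 8 alleles per
#'   locus for 4 founders, forcing full heterozygosity (scenario B).
#'
#' Allele multiplicities beyond these constraints are distributed as evenly
#' as possible (round-robin in allele-label order), a reproducible choice;
#' final-population diversity is insensitive to it.
#'
#' @param n_females,n_males founder counts (defaults 3 and 1).
#' @param ar_per_locus named integer vector of required distinct-allele
#'   counts per locus; default is the published Finnish column
#'   ([finland_allelic_richness()]).
#' @param scheme one of `"max_het"`, `"min_het"`, `"max_ar"`.
#' @return An object of class `founder_spec`.
#' @export
founder_spec <- function(n_females = 3L, n_males = 1L,
                         ar_per_locus = finland_allelic_richness(),
                         scheme = c("max_het", "min_het", "max_ar")) {
  scheme <- match.arg(scheme)
  n <- n_females + n_males
  stopifnot(n_females >= 0, n_males >= 0, n >= 1, length(ar_per_locus) >= 1)
  ar_per_locus <- as.integer(ar_per_locus)
  if (any(ar_per_locus < 1) || any(ar_per_locus > 2L * n))
    stop("each locus must show between 1 and 2 * n_founders alleles")
  if (scheme == "max_ar") ar_per_locus[] <- 2L * n
  if (scheme == "max_het" && any(ar_per_locus == 1L))
    stop("max_het is infeasible at a monomorphic locus (k = 1)")
  loci <- names(ar_per_locus)
  if (is.null(loci)) loci <- paste0("L", seq_along(ar_per_locus))
  structure(list(n_females = as.integer(n_females),
                 n_males = as.integer(n_males),
                 loci = loci, ar_per_locus = setNames(ar_per_locus, loci),
                 scheme = scheme),
            class = "founder_spec")
}

#' Minimal mean founder heterozygosity given allele counts
#'
#' The smallest mean individual heterozygosity `n_founders` diploids can
#' display while carrying exactly `k[i]` distinct alleles at locus `i`:
#' at least `max(0, k - n)` founders must be heterozygous at a locus with
#' `k` alleles (each homozygote displays one allele, each heterozygote at
#' most two novel ones), and that bound is attainable.  Hence
#' \deqn{H_{min} = \sum_i \max(0, k_i - n) / (n L).}
#' With the published Finnish allele counts and 4 founders this is
#' 22/56 = 0.39, the minimal-heterozygosity founding scenario.
#'
#' @param ar_per_locus integer vector of per-locus allele counts `k`.
#' @param n_founders number of founding diploids.
#' @return Fraction in `[0, 1]`.
#' @export
min_founder_heterozygosity <- function(ar_per_locus, n_founders) {
  ar_per_locus <- as.integer(ar_per_locus)
  stopifnot(n_founders >= 1, length(ar_per_locus) >= 1)
  if (any(ar_per_locus < 1) || any(ar_per_locus > 2L * n_founders))
    stop("allele count must lie in [1, 2 * n_founders]")
  sum(pmax(0L, ar_per_locus - n_founders)) / (n_founders * length(ar_per_locus))
}

# deterministic per-locus genotype columns for n founders showing exactly k
# alleles under a scheme; returns 2-row matrix (gene copies) x n columns
founder_locus_alleles <- function(k, n, scheme) {
  if (scheme %in% c("max_het", "max_ar")) {
    # round-robin over allele labels; consecutive labels differ for k >= 2
    g <- rep.int(seq_len(k), ceiling(2 * n / k))[seq_len(2 * n)]
    return(matrix(g, nrow = 2))
  }
  # min_het: max(0, k - n) heterozygotes with two unique alleles each,
  # remaining founders homozygous for the leftover alleles, recycled
  h <- max(0L, k - n)
  het <- if (h > 0) matrix(seq_len(2L * h), nrow = 2) else matrix(integer(), nrow = 2)
  rem <- setdiff(seq_len(k), seq_len(2L * h))
  if (length(rem) == 0) rem <- 1L
  hom_lab <- rep.int(rem, ceiling((n - h) / length(rem)))[seq_len(n - h)]
  cbind(het, matrix(rep(hom_lab, each = 2), nrow = 2))
}

#' Construct founder genotypes for a scenario
#'
#' Builds the founding population (females first, then males, all age 0)
#' with genotypes satisfying the [founder_spec()] constraints exactly: each
#' locus displays exactly the requested number of distinct alleles, and the
#' number of heterozygous founders per locus is maximal (`max_het`,
#' `max_ar`) or minimal (`min_het`).  Construction is deterministic.
#'
#' @param spec a [founder_spec()].
#' @return A `deer_pop` population object (see [population_H()]).
#' @examples
#' f <- build_founders(founder_spec(scheme = "max_ar"))
#' population_AR(f)  # 8 alleles per locus for 4 founders
#' @export
build_founders <- function(spec) {
  stopifnot(inherits(spec, "founder_spec"))
  n <- spec$n_females + spec$n_males
  L <- length(spec$loci)
  a1 <- matrix(0L, n, L, dimnames = list(NULL, spec$loci))
  a2 <- a1
  for (j in seq_len(L)) {
    m <- founder_locus_alleles(spec$ar_per_locus[j], n, spec$scheme)
    a1[, j] <- m[1, ]; a2[, j] <- m[2, ]
  }
  new_deer_pop(a1, a2,
               female = rep(c(TRUE, FALSE), c(spec$n_females, spec$n_males)),
               age = rep(0L, n))
}

#' A scheduled second-introduction event
#'
#' Release of additional animals into the established population at a given
#' time step.  Cohort genotypes follow the conservative "novel and fully
#' heterozygous" assumption: every individual heterozygous at every locus,
#' all alleles new to the population and to each other (so a cohort of 4
#' adds 8 novel alleles per locus).
#'
#' @param time_step simulation year of the release (15 = 1949 for a 1934
#'   founding).
#' @param n_females,n_males cohort composition (defaults 3 and 1, the
#'   recorded 1949 release).
#' @param age_at_release age in years at release (default 1).
#' @return An object of class `introduction_event`.
#' @export
introduction_event <- function(time_step = 15L, n_females = 3L, n_males = 1L,
                               age_at_release = 1L) {
  stopifnot(time_step >= 0, n_females >= 0, n_males >= 0, age_at_release >= 0)
  structure(list(time_step = as.integer(time_step),
                 n_females = as.integer(n_females),
                 n_males = as.integer(n_males),
                 age_at_release = as.integer(age_at_release)),
            class = "introduction_event")
}

#' Build the genotypes of a second-introduction cohort
#'
#' @param event an [introduction_event()].
#' @param loci character vector of locus names.
#' @param existing_labels integer vector (or matrix) of allele labels
#'   already present anywhere in the simulated population; cohort alleles
#'   are chosen strictly above its maximum, hence disjoint from it.
#' @return A `deer_pop` with one fully heterozygous individual per cohort
#'   member, ages set to `age_at_release`.
#' @export
build_introduction_cohort <- function(event, loci, existing_labels) {
  stopifnot(inherits(event, "introduction_event"))
  n <- event$n_females + event$n_males
  L <- length(loci)
  if (n == 0L)
    return(new_deer_pop(matrix(integer(), 0, L, dimnames = list(NULL, loci)),
                        matrix(integer(), 0, L, dimnames = list(NULL, loci)),
                        female = logical(0), age = integer(0)))
  base <- max(0L, existing_labels)
  lab <- base + seq_len(2L * n)
  a1 <- matrix(rep(lab[seq(1, 2 * n, 2)], L), n, L, dimnames = list(NULL, loci))
  a2 <- matrix(rep(lab[seq(2, 2 * n, 2)], L), n, L, dimnames = list(NULL, loci))
  new_deer_pop(a1, a2,
               female = rep(c(TRUE, FALSE), c(event$n_females, event$n_males)),
               age = rep(event$age_at_release, n))
}
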