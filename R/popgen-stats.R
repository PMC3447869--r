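#' Nei's unbiased expected heterozygosity (gene diversity)
#'
#' For sample allele frequencies \eqn{p_i} based on \eqn{n} observed gene
#' copies, the small-sample-corrected gene diversity is
#' \deqn{\hat h = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right),}
#' the quantity conventionally reported for microsatellite surveys (it is
#' what FSTAT prints as gene diversity).  The value is clipped to `[0, 1]`.
#'
#' @param counts named vector of allele counts at one locus (gene copies,
#'   i.e. 2 per diploid individual), or a [genotype_table()] together with
#'   `locus`.
#' @param locus locus name, used only when `counts` is a table.
#' @return Gene diversity estimate in `[0, 1]`; exactly 0 for a
#'   monomorphic locus.
#' @examples
#' expected_heterozygosity(c(A = 72, B = 72))  # two alleles at 0.5, n = 144
#' @export
expected_heterozygosity <- function(counts, locus = NULL) {
  if (inherits(counts, "genotype_table")) counts <- allele_counts(counts, locus)
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("expected heterozygosity is undefined for fewer than 2 gene copies")
  p <- counts / n
  h <- n / (n - 1) * (1 - sum(p^2))
  min(max(h, 0), 1)
}

#' Allelic richness at a locus
#'
#' The number of distinct alleles observed.  With both samples standardised
#' to the same number of fully genotyped individuals (72 here), FSTAT-style
#' rarefaction to the minimal sample size is the identity, so the raw count
#' is reported.
#'
#' @inheritParams expected_heterozygosity
#' @return Positive integer count of distinct alleles.
#' @export
allelic_richness <- function(counts, locus = NULL) {
  if (inherits(counts, "genotype_table")) counts <- allele_counts(counts, locus)
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("no observed alleles at this locus")
  length(counts)
}

#' Observed heterozygosity at a locus
#'
#' Fraction of individuals with complete data at the locus whose two alleles
#' differ.
#'
#' @param table a [genotype_table()].
#' @param locus locus name.
#' @return Fraction in `[0, 1]`.
#' @export
observed_heterozygosity <- function(table, locus) {
  j <- locus_index(table, locus)
  ok <- table$a1[, j] > 0L & table$a2[, j] > 0L
  if (!any(ok)) stop(sprintf("locus '%s' has no complete genotypes", locus))
  mean(table$a1[ok, j] != table$a2[ok, j])
}

#' Per-locus and over-loci diversity summary
#'
#' `locus_summary()` bundles the per-locus allelic richness and expected
#' heterozygosity; `diversity_summary()` computes both for every locus of a
#' genotype table; `summarize_population()` averages a set of per-locus
#' summaries into the over-loci means reported in population surveys.
#'
#' @param locus character locus name(s).
#' @param allele_count integer allelic richness per locus.
#' @param expected_het expected heterozygosity per locus.
#' @return `locus_summary()` and `diversity_summary()` return a data frame
#'   with columns `locus`, `allele_count`, `expected_het`;
#'   `summarize_population()` returns an object of class
#'   `diversity_summary`: a list with `mean_expected_het`,
#'   `mean_allelic_richness` and the `per_locus` data frame.
#' @export
locus_summary <- function(locus, allele_count, expected_het) {
  stopifnot(length(locus) == length(allele_count),
            length(locus) == length(expected_het),
            all(allele_count >= 1),
            all(expected_het >= 0 & expected_het <= 1),
            all(expected_het[allele_count == 1] == 0))
  data.frame(locus = as.character(locus),
             allele_count = as.integer(allele_count),
             expected_het = as.numeric(expected_het),
             stringsAsFactors = FALSE)
}

#' @rdname locus_summary
#' @param table a [genotype_table()].
#' @export
diversity_summary <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  per <- locus_summary(
    table$loci,
    vapply(table$loci, function(l) allelic_richness(table, l), 0L),
    vapply(table$loci, function(l) expected_heterozygosity(table, l), 0))
  summarize_population(per)
}

#' @rdname locus_summary
#' @param per_locus data frame as returned by [locus_summary()].
#' @export
summarize_population <- function(per_locus) {
  if (NROW(per_locus) == 0) stop("at least one locus summary is required")
  stopifnot(all(c("locus", "allele_count", "expected_het") %in% names(per_locus)))
  structure(list(mean_expected_het = mean(per_locus$expected_het),
                 mean_allelic_richness = mean(per_locus$allele_count),
                 per_locus = per_locus),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf("Diversity over %d loci: mean A_R = %.2f, mean H_E = %.3f\n",
              nrow(x$per_locus), x$mean_allelic_richness, x$mean_expected_het))
  invisible(x)
}

#' @export
as.data.frame.diversity_summary <- function(x, ...) {
  rbind(x$per_locus,
        data.frame(locus = "Over loci",
                   allele_count = x$mean_allelic_richness,
                   expected_het = x$mean_expected_het))
}

#' One-tailed Mann-Whitney U test (normal approximation)
#'
#' Rank-sum comparison of two samples using the tie-corrected normal
#' approximation without continuity correction — the convention of the
#' classic SPSS output this mirrors.  `Z` is signed so that a smaller mean
#' rank of `x` gives a negative value, and the one-tailed p-value is
#' `pnorm(Z)`, i.e. for the directional hypothesis that `x` is
#' stochastically smaller than `y`.
#'
#' @param x,y numeric samples (non-empty).
#' @return List with elements `Z`, `p_one_tailed`, and the `U` statistic of
#'   sample `x`.
#' @examples
#' mann_whitney_one_tailed(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney_one_tailed <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  v <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (v > 0) (U - n1 * n2 / 2) / sqrt(v) else 0
  list(Z = z, p_one_tailed = pnorm(z), U = U)
}
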