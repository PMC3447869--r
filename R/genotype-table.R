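#' Multi-locus diploid genotype table
#'
#' Container for co-dominant genotypes of one population sample: two integer
#' allele matrices (individuals x loci), one per gene copy.  Allele labels
#' are positive integers; `0` is the reserved missing-data sentinel (the
#' Genepop `000` convention).  Allele order within an individual carries no
#' meaning.
#'
#' @param a1,a2 integer matrices of identical dimension, one row per
#'   individual, one column per locus; entries are positive allele labels or
#'   `0` for missing.
#' @param loci character vector of locus names (defaults to the column names
#'   of `a1`, else `L1`, `L2`, ...).
#' @param population single character label for the sample.
#' @return An object of class `genotype_table` with elements `a1`, `a2`,
#'   `loci` and `population`.
#' @examples
#' gt <- genotype_table(a1 = matrix(c(1L, 1L), 2), a2 = matrix(c(1L, 2L), 2),
#'                      loci = "K", population = "demo")
#' n_individuals(gt)
#' @export
genotype_table <- function(a1, a2, loci = NULL, population = "pop1") {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!identical(dim(a1), dim(a2)))
    stop("allele matrices must have identical dimensions")
  if (nrow(a1) < 1L || ncol(a1) < 1L)
    stop("a genotype table needs at least one individual and one locus")
  if (anyNA(a1) || anyNA(a2))
    stop("use the 0 sentinel, not NA, for missing alleles")
  if (any(a1 < 0L) || any(a2 < 0L))
    stop("allele labels must be non-negative integers (0 = missing)")
  if (is.null(loci)) loci <- colnames(a1)
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(a1)))
  if (length(loci) != ncol(a1)) stop("length(loci) must match the locus count")
  colnames(a1) <- colnames(a2) <- loci
  structure(list(a1 = a1, a2 = a2, loci = as.character(loci),
                 population = as.character(population)[1]),
            class = "genotype_table")
}

#' @rdname genotype_table
#' @param x a `genotype_table`.
#' @export
n_individuals <- function(x) {
  stopifnot(inherits(x, "genotype_table"))
  nrow(x$a1)
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table '%s': %d individuals x %d loci\n",
              x$population, nrow(x$a1), length(x$loci)))
  cc <- sum(complete_case_mask(x))
  cat(sprintf("  loci: %s\n  complete cases: %d\n",
              paste(head(x$loci, 6), collapse = ", "), cc))
  invisible(x)
}

#' @export
`[.genotype_table` <- function(x, i, ...) {
  genotype_table(x$a1[i, , drop = FALSE], x$a2[i, , drop = FALSE],
                 loci = x$loci, population = x$population)
}

# rows with both alleles observed at every locus
complete_case_mask <- function(table) {
  rowSums(table$a1 == 0L | table$a2 == 0L) == 0L
}

locus_index <- function(table, locus) {
  j <- match(locus, table$loci)
  if (is.na(j)) stop(sprintf("locus '%s' not present in table", locus))
  j
}

#' Observed allele counts at one locus
#'
#' Tallies the observed (non-missing) gene copies at a locus, the raw input
#' for [expected_heterozygosity()] and [allelic_richness()].
#'
#' @param table a [genotype_table()].
#' @param locus locus name.
#' @return Named integer vector of counts per allele label.
#' @export
allele_counts <- function(table, locus) {
  j <- locus_index(table, locus)
  al <- c(table$a1[, j], table$a2[, j])
  al <- al[al > 0L]
  tab <- table(al)
  setNames(as.integer(tab), names(tab))
}

#' Randomly subsample complete-case individuals
#'
#' Draws `n` individuals uniformly without replacement from the rows having
#' no missing data at any locus, as done when matching a sample to the size
#' of a published reference sample (here 72).  The draw is reproducible for
#' a fixed `seed`; the caller's RNG state is left untouched.
#'
#' @inheritParams allele_counts
#' @param n number of individuals to keep (may be 0).
#' @param seed integer seed for the draw.
#' @return A `genotype_table` with exactly `n` rows, all complete cases.
#' @export
subsample_complete_cases <- function(table, n, seed = 1L) {
  stopifnot(inherits(table, "genotype_table"), n >= 0L)
  keep <- which(complete_case_mask(table))
  if (length(keep) < n)
    stop(sprintf("only %d complete cases available, %d requested",
                 length(keep), n))
  if (n == 0L) {
    out <- table
    out$a1 <- table$a1[0L, , drop = FALSE]
    out$a2 <- table$a2[0L, , drop = FALSE]
    return(out)
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sel <- keep[sample.int(length(keep), n)]
  table[sel]
}
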