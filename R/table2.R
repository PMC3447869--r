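#' Published per-locus diversity of the Finnish and Oklahoma samples
#'
#' Per-locus allelic richness and expected heterozygosity for the 14
#' microsatellite loci scored in 72 fully genotyped white-tailed deer from
#' each of the Finnish (introduced, 2009-2011) and Oklahoma (reference
#' North-American) populations, as published.  These printed summaries are
#' the package's empirical anchor: raw genotypes were never deposited, so
#' per-locus values — not genotypes — are what ships.
#'
#' @param population `"finland"`, `"oklahoma"`, or `"both"`.
#' @return A data frame with columns `locus`, `population`, `allele_count`
#'   and `expected_het` (a [locus_summary()]-shaped table when a single
#'   population is selected).
#' @examples
#' summarize_population(published_diversity("finland"))
#' @export
published_diversity <- function(population = c("finland", "oklahoma", "both")) {
  population <- match.arg(population)
  path <- system.file("extdata", "table2_per_locus.csv",
                      package = "founderdrift", mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (population == "both") return(tab)
  tab <- tab[tab$population == population, c("locus", "allele_count", "expected_het")]
  rownames(tab) <- NULL
  tab
}

#' Allelic richness of the Finnish sample, per locus
#'
#' Convenience accessor for the published Finnish allele counts, the
#' default per-locus richness constraint for founder construction.
#'
#' @return Named integer vector (14 loci).
#' @export
finland_allelic_richness <- function() {
  tab <- published_diversity("finland")
  setNames(as.integer(tab$allele_count), tab$locus)
}
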