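# Independent brute-force oracles and shared fixtures for the suite.

# published per-locus columns used throughout
fin_tab <- published_diversity("finland")
okl_tab <- published_diversity("oklahoma")

# small genotype table: one individual per row of `pairs` (list of c(a1, a2)
# per locus)
gt_from_pairs <- function(..., loci = NULL) {
  rows <- list(...)
  a1 <- do.call(rbind, lapply(rows, function(r) vapply(r, `[`, integer(1), 1L)))
  a2 <- do.call(rbind, lapply(rows, function(r) vapply(r, `[`, integer(1), 2L)))
  genotype_table(a1, a2, loci = loci)
}

# exhaustive search: minimal number of heterozygous founders among n diploids
# constrained to display exactly k distinct alleles at one locus
brute_min_het_founders <- function(k, n) {
  copies <- 2L * n
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), copies)))
  shows_k <- apply(grid, 1, function(g) length(unique(g)) == k)
  grid <- grid[shows_k, , drop = FALSE]
  odd <- seq(1, copies, 2)
  min(rowSums(grid[, odd, drop = FALSE] != grid[, odd + 1, drop = FALSE]))
}

# exact one-tailed Mann-Whitney p by enumeration of all group labelings,
# with the mid-p tie convention (half weight on rank sums equal to the
# observed one) — the exact counterpart of the normal approximation
# without continuity correction
exact_mw_p <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n1)])
  cmb <- utils::combn(length(r), n1)
  sums <- colSums(matrix(r[cmb], nrow = n1))
  mean(sums < obs) + 0.5 * mean(sums == obs)
}

# simulation runs reused across test files (one cache per test session)
.sim_cache <- new.env(parent = emptyenv())
cached_scenario <- function(scheme, n_replicates = 300L, seed = 101L) {
  key <- paste(scheme, n_replicates, seed, sep = "_")
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- run_scenario(scheme, n_replicates = n_replicates,
                                      seed = seed)
  .sim_cache[[key]]
}
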