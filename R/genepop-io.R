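#' Read and write genotype tables in Genepop format
#'
#' Minimal, strict Genepop dialect: a title line, one locus name per line
#' (or one comma-separated line), `Pop` markers, then one individual per
#' line as `id ,  aaabbb aaabbb ...` with fixed-width 2- or 3-digit allele
#' codes (`00`/`000` = missing).  Only the first `Pop` block is returned by
#' default; set `pop` to choose another.
#'
#' @param path file path.
#' @param pop index of the population block to return.
#' @return A [genotype_table()]; the population label is the text before
#'   the comma of the block's first individual line, else `popN`.
#' @export
read_genepop <- function(path, pop = 1L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) < 3) stop("not a Genepop file: fewer than 3 lines")
  body <- lines[-1]
  is_pop <- toupper(trimws(body)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("not a Genepop file: no 'Pop' line found")
  loci_lines <- body[seq_len(first_pop - 1)]
  loci <- trimws(unlist(strsplit(loci_lines, ",")))
  loci <- loci[loci != ""]
  if (length(loci) == 0) stop("no locus names before the first 'Pop'")
  n_blocks <- sum(is_pop)
  if (pop > n_blocks) stop(sprintf("file has %d Pop block(s), %d requested",
                                   n_blocks, pop))
  idx <- which(!is_pop & cumsum(is_pop) == pop)
  if (length(idx) == 0) stop(sprintf("Pop block %d is empty", pop))
  n <- length(idx); L <- length(loci)
  a1 <- matrix(0L, n, L); a2 <- matrix(0L, n, L)
  label <- NULL
  for (i in seq_len(n)) {
    ln <- body[idx[i]]
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2)
      stop(sprintf("line %d: expected 'id , genotypes' but found no comma",
                   idx[i] + 1L))
    if (is.null(label)) label <- trimws(parts[1])
    gts <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[ \t]+")[[1]]
    if (length(gts) != L)
      stop(sprintf("line %d: %d genotypes found, %d loci declared",
                   idx[i] + 1L, length(gts), L))
    w <- nchar(gts)
    if (any(w != w[1]) || !w[1] %in% c(4L, 6L))
      stop(sprintf("line %d: allele codes must be uniformly 2- or 3-digit",
                   idx[i] + 1L))
    d <- w[1] / 2
    a1[i, ] <- as.integer(substr(gts, 1, d))
    a2[i, ] <- as.integer(substr(gts, d + 1, 2 * d))
  }
  if (anyNA(a1) || anyNA(a2)) stop("non-numeric allele code encountered")
  genotype_table(a1, a2, loci = loci,
                 population = if (nzchar(label)) label else paste0("pop", pop))
}

#' @rdname read_genepop
#' @param table a [genotype_table()].
#' @param title title line written at the top of the file.
#' @param digits width of one allele code (2 or 3).
#' @export
write_genepop <- function(table, path, title = table$population, digits = 3L) {
  stopifnot(inherits(table, "genotype_table"), digits %in% c(2L, 3L))
  if (any(table$a1 >= 10^digits) || any(table$a2 >= 10^digits))
    stop("allele labels too large for the chosen code width")
  fmt <- paste0("%0", digits, "d%0", digits, "d")
  rows <- vapply(seq_len(nrow(table$a1)), function(i) {
    paste0(table$population, "_", i, " ,  ",
           paste(sprintf(fmt, table$a1[i, ], table$a2[i, ]), collapse = " "))
  }, "")
  writeLines(c(title, table$loci, "Pop", rows), path)
  invisible(path)
}

#' Read and write genotype tables as wide CSV
#'
#' One row per individual with an `id` column and two columns per locus
#' named `<locus>.1` and `<locus>.2`; `0` or an empty cell means missing.
#'
#' @param path file path.
#' @param population label for the returned table.
#' @return A [genotype_table()].
#' @export
read_genotype_csv <- function(path, population = "pop1") {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cols <- setdiff(names(df), "id")
  loci <- unique(sub("\\.[12]$", "", cols))
  need <- c(paste0(loci, ".1"), paste0(loci, ".2"))
  if (!all(need %in% cols))
    stop("each locus needs paired columns '<locus>.1' and '<locus>.2'")
  a1 <- as.matrix(df[, paste0(loci, ".1"), drop = FALSE])
  a2 <- as.matrix(df[, paste0(loci, ".2"), drop = FALSE])
  a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
  genotype_table(a1, a2, loci = loci, population = population)
}

#' @rdname read_genotype_csv
#' @param table a [genotype_table()].
#' @export
write_genotype_csv <- function(table, path) {
  stopifnot(inherits(table, "genotype_table"))
  df <- data.frame(id = paste0(table$population, "_", seq_len(nrow(table$a1))))
  for (j in seq_along(table$loci)) {
    df[[paste0(table$loci[j], ".1")]] <- table$a1[, j]
    df[[paste0(table$loci[j], ".2")]] <- table$a2[, j]
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a diversity summary to disk
#'
#' `write_diversity_json()` serialises the full summary;
#' `write_diversity_csv()` writes the per-locus table with an appended
#' `Over loci` row, mirroring the layout of published survey tables
#' (heterozygosities to 3 decimals, over-loci means to 2).
#'
#' @param summary a `diversity_summary` (see [summarize_population()]).
#' @param path output file path.
#' @export
write_diversity_json <- function(summary, path) {
  stopifnot(inherits(summary, "diversity_summary"))
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_diversity_json
#' @export
write_diversity_csv <- function(summary, path) {
  stopifnot(inherits(summary, "diversity_summary"))
  df <- summary$per_locus
  df$expected_het <- sprintf("%.3f", df$expected_het)
  df <- rbind(df, data.frame(
    locus = "Over loci",
    allele_count = sprintf("%.2f", summary$mean_allelic_richness),
    expected_het = sprintf("%.3f", summary$mean_expected_het)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
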