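#' Genotype matrix container
#'
#' A `geno_matrix` is a numeric matrix of biallelic SNP calls coded
#' `-1/0/+1` (minor-allele dose minus one; `0` is a heterozygote; `NA` is
#' missing) with lines in rows and markers in columns, carrying two pieces of
#' metadata: a marker map (`marker`, `chrom`, `pos_cm`) and a line table
#' (`line`, `population`, `parent1`, `parent2`). All downstream results
#' derived from it (QC summaries, LD, kinship, PCA, cross-validation) are
#' returned as tibbles.
#'
#' @param calls Numeric matrix, lines x markers, values in `{-1, 0, 1, NA}`.
#' @param map Data frame with columns `marker`, `chrom`, `pos_cm`, one row
#'   per column of `calls`, in column order.
#' @param lines Data frame with columns `line`, `population`, `parent1`,
#'   `parent2`, one row per row of `calls`, in row order.
#' @return A `geno_matrix` object.
#' @export
geno_matrix <- function(calls, map, lines) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "double"
  map <- as_tibble(map)
  lines <- as_tibble(lines)
  stopifnot(
    nrow(map) == ncol(calls),
    nrow(lines) == nrow(calls),
    all(c("marker", "chrom", "pos_cm") %in% names(map)),
    all(c("line", "population") %in% names(lines))
  )
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% c(-1, 0, 1))) {
    abort("genotype calls must be coded -1/0/+1 with NA for missing")
  }
  if (anyDuplicated(map$marker)) abort("duplicated marker ids in map")
  if (!"parent1" %in% names(lines)) lines$parent1 <- NA_character_
  if (!"parent2" %in% names(lines)) lines$parent2 <- NA_character_
  dimnames(calls) <- list(lines$line, map$marker)
  structure(calls, map = map, line_info = lines,
            class = c("geno_matrix", "matrix", "array"))
}

#' @export
print.geno_matrix <- function(x, ...) {
  li <- line_info(x)
  cat(sprintf(
    "<geno_matrix> %d lines x %d markers (%d chromosomes), %.1f%% missing\n",
    nrow(x), ncol(x), length(unique(marker_map(x)$chrom)),
    100 * mean(is.na(unclass(x)))
  ))
  pops <- table(li$population)
  cat("populations:", paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
  invisible(x)
}

#' Marker map and line metadata of a genotype matrix
#' @param geno A [geno_matrix()].
#' @return A tibble (`marker`/`chrom`/`pos_cm`, or `line`/`population`/parents).
#' @export
marker_map <- function(geno) attr(geno, "map")

#' @rdname marker_map
#' @export
line_info <- function(geno) attr(geno, "line_info")

#' @export
`[.geno_matrix` <- function(x, i, j, ..., drop = FALSE) {
  m <- unclass(x)
  out <- m[i, j, drop = FALSE]
  map <- marker_map(x)
  li <- line_info(x)
  if (!missing(j)) {
    jj <- if (is.character(j)) match(j, colnames(m)) else seq_len(ncol(m))[j]
    map <- map[jj, ]
  }
  if (!missing(i)) {
    ii <- if (is.character(i)) match(i, rownames(m)) else seq_len(nrow(m))[i]
    li <- li[ii, ]
  }
  geno_matrix(out, map, li)
}

# plain numeric matrix (drops metadata)
geno_calls <- function(geno) {
  m <- unclass(geno)
  attr(m, "map") <- NULL
  attr(m, "line_info") <- NULL
  m
}

#' Select a subset of markers by id
#'
#' @param geno A [geno_matrix()].
#' @param markers Character vector of marker ids (order as given in the
#'   genome map, not as listed).
#' @return A `geno_matrix` restricted to those markers, in genome order.
#' @export
select_markers <- function(geno, markers) {
  missing_ids <- setdiff(markers, marker_map(geno)$marker)
  if (length(missing_ids)) {
    abort(sprintf("markers not present: %s",
                  paste(head(missing_ids, 5), collapse = ", ")))
  }
  keep <- marker_map(geno)$marker %in% markers
  geno[, keep]
}

#' Per-marker summaries: allele frequency, MAF, heterozygosity, missingness
#'
#' Frequencies are computed on non-missing calls only; `p` is the frequency
#' of the `+1` allele and `maf = min(p, 1 - p)`.
#'
#' @param geno A [geno_matrix()].
#' @return A tibble with one row per marker: `marker`, `chrom`, `pos_cm`,
#'   `p`, `maf`, `het`, `missing`.
#' @export
marker_stats <- function(geno) {
  m <- geno_calls(geno)
  n_obs <- colSums(!is.na(m))
  p <- colMeans(m + 1, na.rm = TRUE) / 2
  p[n_obs == 0] <- NA_real_
  het <- colMeans(m == 0, na.rm = TRUE)
  het[n_obs == 0] <- NA_real_
  mutate(marker_map(geno),
         p = unname(p),
         maf = pmin(.data$p, 1 - .data$p),
         het = unname(het),
         missing = unname(1 - n_obs / nrow(m)))
}

# per-marker mean imputation; returns plain matrix
impute_marker_means <- function(geno) {
  m <- geno_calls(geno)
  if (anyNA(m)) {
    mu <- colMeans(m, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- mu[idx[, 2]]
  }
  m
}
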