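# recombination fractions between adjacent markers under Haldane's map
# function (no interference): r = (1 - exp(-2d/100)) / 2 for d in cM
haldane_r <- function(d_cm) 0.5 * (1 - exp(-2 * d_cm / 100))

# per-chromosome layout used by the meiosis kernel
chrom_blocks <- function(map) {
  idx <- split(seq_len(nrow(map)), map$chrom)
  lapply(idx, function(ii) {
    list(cols = ii, r = haldane_r(diff(map$pos_cm[ii])))
  })
}

# One meiosis for n individuals at once. h1, h2: n x m 0/1 haplotype
# matrices. Returns an n x m gamete matrix: a recombinant mosaic of the two
# haplotypes with crossover locations from independent Bernoulli(r) draws
# per marker interval (Haldane: no interference), independent chromosomes.
meiosis_gametes <- function(h1, h2, blocks) {
  n <- nrow(h1)
  chooser <- matrix(0L, n, ncol(h1))
  for (b in blocks) {
    m_b <- length(b$cols)
    start <- rbinom(n, 1L, 0.5)
    if (m_b == 1L) {
      chooser[, b$cols] <- start
    } else {
      sw <- matrix(rbinom(n * (m_b - 1L), 1L, rep(b$r, each = n)),
                   nrow = n)
      cum <- cbind(start, sw)
      cum <- t(apply(cum, 1L, cumsum)) %% 2L
      chooser[, b$cols] <- cum
    }
  }
  h1 * (1L - chooser) + h2 * chooser
}

#' Simulate a bi-parental RIL family by single-seed descent
#'
#' Crosses two fully inbred parents and advances each line from the F1 by
#' `selfing_generations` rounds of selfing with a single offspring carried
#' per generation (single-seed descent). Recombination follows the genetic
#' map under Haldane's map function. Residual heterozygosity is retained:
#' after `t` selfing generations the expected per-locus heterozygosity at
#' loci segregating in the cross is `(1/2)^t` (the default `t = 6` emulates
#' F5:7 lines at about 1.6%).
#'
#' @param parent_a,parent_b Haplotypes of the two inbred parents: 0/1
#'   vectors of length `nrow(map)` (e.g. rows of a [sim_founders()] pool).
#' @param n_lines Number of RILs to derive.
#' @param map Genetic map tibble (`marker`, `chrom`, `pos_cm`).
#' @param selfing_generations Selfing rounds from the F1 (>= 1).
#' @param family Population label for the line metadata.
#' @param parents Character length-2 with parent ids recorded in the line
#'   metadata (full-sib bookkeeping for across-family cross-validation).
#' @param seed Integer seed.
#' @return A [geno_matrix()] of `n_lines` lines coded -1/0/+1.
#' @export
sim_biparental_rils <- function(parent_a, parent_b, n_lines, map,
                                selfing_generations = 6L, family = "Pop1",
                                parents = c("parentA", "parentB"),
                                seed = 1L) {
  stopifnot(selfing_generations >= 1, n_lines >= 1)
  parent_a <- as.integer(parent_a)
  parent_b <- as.integer(parent_b)
  m <- nrow(map)
  if (length(parent_a) != m || length(parent_b) != m ||
      !all(c(parent_a, parent_b) %in% c(0L, 1L))) {
    abort("parents must be fully inbred 0/1 haplotypes matching the map")
  }
  if (all(parent_a == parent_b)) {
    warn(sprintf("parents of %s are identical at all markers; family is monomorphic",
                 family))
  }
  blocks <- chrom_blocks(map)
  ones <- matrix(1L, n_lines, 1L)
  # F1 for every line: one parental haplotype each
  h1 <- ones %*% matrix(parent_a, 1L)
  h2 <- ones %*% matrix(parent_b, 1L)
  with_seed(derive_seed(seed, "ssd", family), {
    for (t in seq_len(selfing_generations)) {
      g1 <- meiosis_gametes(h1, h2, blocks)
      g2 <- meiosis_gametes(h1, h2, blocks)
      h1 <- g1
      h2 <- g2
    }
  })
  calls <- h1 + h2 - 1L
  lines <- tibble(
    line = sprintf("%s_%03d", family, seq_len(n_lines)),
    population = family,
    parent1 = parents[1],
    parent2 = parents[2]
  )
  geno_matrix(calls, map, lines)
}

#' Stack several genotype matrices over a shared map
#'
#' @param ... [geno_matrix()] objects with identical marker maps.
#' @return A single [geno_matrix()] with the line tables concatenated.
#' @export
bind_geno <- function(...) {
  gs <- list(...)
  if (length(gs) == 1L && is.list(gs[[1]]) && !inherits(gs[[1]], "geno_matrix")) {
    gs <- gs[[1]]
  }
  map <- marker_map(gs[[1]])
  for (g in gs[-1]) {
    if (!identical(marker_map(g)$marker, map$marker)) {
      abort("all genotype matrices must share the same marker map")
    }
  }
  calls <- do.call(rbind, lapply(gs, geno_calls))
  lines <- list_rbind(lapply(gs, line_info))
  if (anyDuplicated(lines$line)) abort("duplicated line ids across matrices")
  geno_matrix(calls, map, lines)
}
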