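# small fixtures shared across test files; everything is built in code

tiny_map <- function(n_chrom = 2, m = 10, len = 100) {
  sim_genetic_map(n_chrom = n_chrom, markers_per_chrom = m,
                  chrom_length_cm = len)
}

# wrap a bare matrix as a geno_matrix with a trivial map (one chromosome,
# 1 cM spacing) and one population per supplied label
toy_geno <- function(calls, population = "PopX") {
  calls <- as.matrix(calls)
  if (is.null(colnames(calls))) {
    colnames(calls) <- sprintf("m%02d", seq_len(ncol(calls)))
  }
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("L%03d", seq_len(nrow(calls)))
  }
  map <- tibble::tibble(marker = colnames(calls), chrom = 1L,
                        pos_cm = seq_len(ncol(calls)))
  lines <- tibble::tibble(line = rownames(calls),
                          population = rep_len(population, nrow(calls)),
                          parent1 = NA_character_, parent2 = NA_character_)
  geno_matrix(calls, map, lines)
}

# two-family RIL panel used by several gblup/cv tests
small_panel <- function(seed = 1, n_per_fam = 40, map = tiny_map(4, 30)) {
  pool <- sim_founders(8, map, seed = seed)
  fams <- lapply(1:2, function(f) {
    sim_biparental_rils(pool$alleles[2 * f - 1, ], pool$alleles[2 * f, ],
                        n_per_fam, map, family = paste0("Pop", f),
                        parents = rownames(pool$alleles)[c(2 * f - 1, 2 * f)],
                        seed = seed + f)
  })
  bind_geno(fams)
}

# dense, independent evaluation of the restricted log-likelihood of
# y = 1 mu + g + e, g ~ N(0, K sa), e ~ N(0, I se), profiled over sa at a
# given delta = se/sa; used as the grid oracle for spectral_reml()
dense_profiled_rll <- function(y, K, delta) {
  n <- length(y)
  H <- K + delta * diag(n)
  Hi <- solve(H)
  one <- rep(1, n)
  mu <- sum(Hi %*% y) / sum(Hi %*% one)
  r <- y - mu
  ypy <- drop(t(r) %*% Hi %*% r)
  sa <- ypy / (n - 1)
  -0.5 * ((n - 1) * log(sa) + determinant(H)$modulus[1] +
            log(drop(t(one) %*% Hi %*% one)) + (n - 1) +
            (n - 1) * log(2 * pi))
}
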