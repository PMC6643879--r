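test_that("founder sampling follows the base-frequency spectrum and is reproducible", {
  map <- tiny_map(1, 3)
  p1 <- sim_founders(4, map, c(0.4, 0.5), seed = 7)
  p2 <- sim_founders(4, map, c(0.4, 0.5), seed = 7)
  expect_identical(p1$alleles, p2$alleles)
  expect_true(all(p1$alleles %in% c(0L, 1L)))

  # binomial oracle: empirical frequency within 3 SE of the spectrum draw
  # (independent-founder mode)
  p_big <- sim_founders(1000, tiny_map(1, 5),
                        maf_spectrum = function(n) rep(0.3, n),
                        n_ancestors = 0, seed = 3)
  freq <- colMeans(p_big$alleles)
  se <- sqrt(0.3 * 0.7 / 1000)
  expect_true(all(abs(freq - 0.3) < 3 * se))

  expect_error(
    sim_founders(4, map, maf_spectrum = function(n) rep(1, n)),
    "strictly inside"
  )
})

test_that("mosaic founders share long ancestral haplotypes", {
  map <- tiny_map(2, 100)
  pool <- sim_founders(20, map, n_ancestors = 3, segment_cm = 40, seed = 2)
  # adjacent-marker allelic correlation across founders should be high
  a <- pool$alleles
  keep <- apply(a, 2, sd) > 0
  r <- diag(cor(a[, which(keep)[-sum(keep)]], a[, which(keep)[-1]]))
  expect_gt(mean(r^2, na.rm = TRUE), 0.3)
})

test_that("RIL simulation respects the map: zero distance, monomorphic markers, determinism", {
  map <- tibble::tibble(marker = c("a", "b", "c"), chrom = 1L,
                        pos_cm = c(10, 10, 60))
  pa <- c(0L, 0L, 0L)
  pb <- c(1L, 1L, 0L)
  g <- sim_biparental_rils(pa, pb, 200, map, seed = 5)
  m <- unclass(g)
  # zero distance: no recombinants between a and b
  expect_true(all(m[, "a"] == m[, "b"]))
  # marker monomorphic between parents stays monomorphic
  expect_true(all(m[, "c"] == -1))
  g2 <- sim_biparental_rils(pa, pb, 200, map, seed = 5)
  expect_identical(unclass(g2), m)
  expect_warning(sim_biparental_rils(pa, pa, 5, map, seed = 1), "identical")
})

test_that("selfing heterozygosity follows the (1/2)^t closed form", {
  # >= 5000 segregating loci on *independent* chromosomes (one marker
  # each), so the binomial 3-SE oracle applies
  map <- sim_genetic_map(n_chrom = 60, markers_per_chrom = 1)
  pa <- rep(0L, 60)
  pb <- rep(1L, 60)
  for (t in c(2, 4, 6)) {
    g <- sim_biparental_rils(pa, pb, 100, map, selfing_generations = t,
                             seed = 20 + t)
    het <- mean(unclass(g) == 0)  # 6000 line-by-locus calls
    p_exp <- 0.5^t
    se <- sqrt(p_exp * (1 - p_exp) / length(g))
    expect_lt(abs(het - p_exp), 3 * se + 1e-12)
  }
})

test_that("recombination matches a brute-force gamete-by-gamete oracle at 50 cM", {
  map <- tibble::tibble(marker = c("a", "b"), chrom = 1L, pos_cm = c(0, 50))
  r <- 0.5 * (1 - exp(-2 * 50 / 100))  # Haldane ~ 0.3161
  # brute-force meiosis oracle: walk the SSD pedigree locus pair by locus
  # pair, one gamete at a time (independent of the package's kernel)
  ssd_pair <- function(t) {
    h1 <- c(0L, 0L); h2 <- c(1L, 1L)
    gam <- function(h1, h2) {
      z1 <- sample(0:1, 1)
      z2 <- if (runif(1) < r) 1L - z1 else z1
      c(if (z1 == 0) h1[1] else h2[1], if (z2 == 0) h1[2] else h2[2])
    }
    for (i in seq_len(t)) {
      g1 <- gam(h1, h2); g2 <- gam(h1, h2)
      h1 <- g1; h2 <- g2
    }
    h1 + h2 - 1L
  }
  set.seed(42)
  oracle <- t(replicate(4000, ssd_pair(6)))
  g <- sim_biparental_rils(c(0L, 0L), c(1L, 1L), 4000, map, seed = 9)
  m <- unclass(g)
  r_pkg <- cor(m[, 1], m[, 2])
  r_orc <- cor(oracle[, 1], oracle[, 2])
  # Monte-Carlo error of a correlation at n = 4000
  expect_lt(abs(r_pkg - r_orc), 4 / sqrt(4000))
})

test_that("family genotype frequencies approach the 1:1 homozygote split", {
  map <- sim_genetic_map(n_chrom = 2, markers_per_chrom = 40)
  g <- sim_biparental_rils(rep(0L, 80), rep(1L, 80), 300, map,
                           selfing_generations = 8, seed = 4)
  m <- unclass(g)
  expect_lt(mean(m == 0), 0.01)
  frac_plus <- mean(m[m != 0] == 1)
  expect_lt(abs(frac_plus - 0.5), 0.02)
})

test_that("trait architectures validate inputs and record targets", {
  map <- tiny_map(1, 10)
  expect_error(sim_trait_architecture(map, 0, 0.5), "n_qtl = 0")
  expect_error(sim_trait_architecture(map, 20, 0.5), "exceeds")
  a <- sim_trait_architecture(map, 3, 0.8, seed = 2)
  expect_identical(a, sim_trait_architecture(map, 3, 0.8, seed = 2))
  expect_equal(a$h2_target, 0.8)
})

test_that("genetic values equal the QTL dot product plus offsets", {
  g <- toy_geno(matrix(c(1, -1, 0, 1, -1, 1), nrow = 2, byrow = TRUE))
  arch <- list(qtl = tibble::tibble(marker = c("m01", "m03"),
                                    effect = c(2.5, -1)),
               h2_target = 0.5, pop_offsets = c(PopX = 10), trait = "t")
  class(arch) <- "trait_arch"
  gv <- genetic_values(g, arch)
  expect_equal(gv$g, c(10 + 2.5 * 1 - 1 * 0, 10 + 2.5 * 1 - 1 * 1))

  # zero effects -> offsets only
  arch0 <- arch
  arch0$qtl$effect <- c(0, 0)
  expect_equal(genetic_values(g, arch0)$g, c(10, 10))

  # random instance vs an independent dot-product oracle, with missing
  # QTL calls mean-imputed
  set.seed(1)
  calls <- matrix(sample(c(-1, 0, 1, NA), 20 * 8, TRUE,
                         prob = c(.45, .05, .45, .05)), 20, 8)
  gr <- toy_geno(calls)
  eff <- rnorm(8)
  archr <- list(qtl = tibble::tibble(marker = colnames(unclass(gr)),
                                     effect = eff),
                h2_target = 0.5, pop_offsets = c(), trait = "t")
  class(archr) <- "trait_arch"
  imp <- apply(calls, 2, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x
  })
  expect_equal(genetic_values(gr, archr)$g, drop(imp %*% eff))
})

test_that("trial simulation produces the declared variance structure", {
  gv <- tibble::tibble(line = sprintf("L%02d", 1:60), population = "PopX",
                       g = rnorm(60))
  expect_error(sim_trials(gv, h2_target = 0.2, gxe_vc = 20), "gxe_vc too large")

  # nearly noiseless limit: phenotype tracks mu + g in every plot
  ph0 <- sim_trials(gv, h2_target = 0.9999, n_env = 2, env_vc = 0,
                    gxe_vc = 0, set_vc = 0, mu = 5, seed = 1)
  joined <- dplyr::left_join(ph0, gv, by = "line")
  expect_lt(max(abs(joined$value - 5 - joined$g)), 0.2)

  # environment-effect variance: between-environment mean differences
  # match the configured component (empirical variance oracle); high
  # h2_target keeps the calibrated plot residual out of the env means
  ph <- sim_trials(gv, h2_target = 0.99, n_env = 200, env_vc = 1,
                   gxe_vc = 0, set_vc = 0, seed = 2)
  env_means <- tapply(ph$value, ph$env, mean)
  expect_lt(abs(var(env_means) / var(gv$g) - 1), 0.35)

  # RCBD layout: every line once per block per environment
  counts <- dplyr::count(ph0, line, env, block)
  expect_true(all(counts$n == 1))
})

test_that("the full dataset generator is deterministic and structured", {
  map <- tiny_map(3, 25)
  sim1 <- sim_gs_dataset(family_size = 25, n_mixed = 20, n_founders = 12,
                         map = map, seed = 99)
  sim2 <- sim_gs_dataset(family_size = 25, n_mixed = 20, n_founders = 12,
                         map = map, seed = 99)
  expect_identical(unclass(sim1$geno), unclass(sim2$geno))
  expect_identical(sim1$pheno, sim2$pheno)

  # PCA separates families: positive mean silhouette on PC1-2
  g <- marker_qc(sim1$geno)
  pc <- genotype_pca(g, n_pc = 2)
  sc <- pc$scores
  fams <- grep("^Pop", sc$population)
  d <- as.matrix(dist(as.matrix(sc[fams, c("PC1", "PC2")])))
  lab <- sc$population[fams]
  sil <- vapply(seq_along(lab), function(i) {
    same <- lab == lab[i]
    a <- sum(d[i, same]) / (sum(same) - 1)  # d[i, i] = 0
    b <- min(tapply(d[i, !same], lab[!same], mean))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)

  # divergent trait: Pop1 oil mean sits above the other families
  oil <- dplyr::filter(sim1$truth, trait == "oil")
  mu_pop <- tapply(oil$g, oil$population, mean)
  expect_true(all(mu_pop["Pop1"] > mu_pop[c("Pop2", "Pop3", "Pop4")]))
})
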