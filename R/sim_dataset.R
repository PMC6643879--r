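#' Simulate a full genomic-selection dataset
#'
#' Generates a breeding-program panel with the structure the downstream
#' analysis assumes: four bi-parental F5:7-like RIL families (single-seed
#' descent, residual heterozygosity ~1.6%) of `family_size` lines each, plus
#' a block of advanced lines from many small mixed pedigrees; ~2,600 markers
#' on 20 chromosomes; and three traits spanning the architectures of seed
#' protein, seed oil, and yield: two high-heritability traits (one with
#' between-population mean divergence, the "oil" pattern where Pop1 sits
#' above the other families) and one low-heritability trait. Plot-level
#' phenotypes come from multi-environment RCBD trials with G-by-E.
#'
#' QTL effects are rescaled so the panel-wide genetic variance of each trait
#' (offsets excluded) is 1; population offsets are therefore in genetic-SD
#' units.
#'
#' @param n_families Number of bi-parental RIL families.
#' @param family_size Lines per family.
#' @param n_mixed Number of advanced mixed-pedigree lines.
#' @param n_mixed_pedigrees Number of distinct mixed pedigrees.
#' @param n_fullsib_mixed Number of mixed pedigrees that reuse the parent
#'   pair of a bi-parental family (their lines are then full sibs of that
#'   family; the study design removes such overlap, so the default is 0).
#' @param map Genetic map; default [sim_genetic_map()] (20 x 130 x 100 cM).
#' @param n_founders Size of the founder pool.
#' @param maf_spectrum Base-frequency range for [sim_founders()].
#' @param n_ancestors,segment_cm Ancestral-haplotype mosaic settings for
#'   [sim_founders()]; they control panel-wide LD and family divergence.
#' @param selfing_generations Selfing rounds from the F1.
#' @param traits Named list of trait settings; each element is a list with
#'   `h2`, `n_qtl`, `pop_offsets`, `mu`. See defaults in the function.
#' @param n_env,n_blocks Trial dimensions passed to [sim_trials()].
#' @param missing_rate Fraction of genotype calls set missing at random.
#' @param seed Master seed; all stages derive child seeds from it.
#' @return A list of class `gs_sim`: `geno` ([geno_matrix()]), `pheno`
#'   (long plot-level tibble), `arch` (list of trait architectures),
#'   `truth` (tibble `line`, `population`, `trait`, `g` of true genetic
#'   values), and `h2_target` (named vector).
#' @export
#' @examples
#' sim <- sim_gs_dataset(family_size = 12, n_mixed = 12, n_founders = 10,
#'                       map = sim_genetic_map(n_chrom = 3, markers_per_chrom = 20),
#'                       seed = 7)
#' sim$geno
sim_gs_dataset <- function(n_families = 4, family_size = 84, n_mixed = 150,
                           n_mixed_pedigrees = 15, n_fullsib_mixed = 0,
                           map = sim_genetic_map(),
                           n_founders = 40, maf_spectrum = c(0.2, 0.5),
                           n_ancestors = 4, segment_cm = 40,
                           selfing_generations = 6,
                           traits = default_trait_settings(),
                           n_env = 4, n_blocks = 2,
                           missing_rate = 0.02, seed = 1L) {
  stopifnot(n_founders >= 2 * n_families + 2,
            n_fullsib_mixed <= min(n_families, n_mixed_pedigrees))
  pool <- sim_founders(n_founders, map, maf_spectrum,
                       n_ancestors = n_ancestors, segment_cm = segment_cm,
                       seed = derive_seed(seed, "pool"))
  founder_ids <- rownames(pool$alleles)

  fam_parents <- matrix(founder_ids[seq_len(2 * n_families)], ncol = 2,
                        byrow = TRUE)
  fams <- purrr::map(seq_len(n_families), function(f) {
    sim_biparental_rils(
      pool$alleles[fam_parents[f, 1], ], pool$alleles[fam_parents[f, 2], ],
      n_lines = family_size, map = map,
      selfing_generations = selfing_generations,
      family = paste0("Pop", f), parents = fam_parents[f, ],
      seed = derive_seed(seed, "fam", f)
    )
  })

  # mixed pedigrees: small families from the remaining founders; the first
  # n_fullsib_mixed pedigrees reuse a bi-parental family's parent pair
  mixed <- list()
  if (n_mixed > 0) {
    sizes <- diff(round(seq(0, n_mixed, length.out = n_mixed_pedigrees + 1)))
    spare <- founder_ids[-seq_len(2 * n_families)]
    pairs <- with_seed(derive_seed(seed, "mixedpairs"), {
      lapply(seq_len(n_mixed_pedigrees), function(p) {
        if (p <= n_fullsib_mixed) fam_parents[p, ] else sample(spare, 2)
      })
    })
    mixed <- purrr::map(seq_len(n_mixed_pedigrees), function(p) {
      if (sizes[p] == 0) return(NULL)
      sim_biparental_rils(
        pool$alleles[pairs[[p]][1], ], pool$alleles[pairs[[p]][2], ],
        n_lines = sizes[p], map = map,
        selfing_generations = selfing_generations + 1,  # F5:8-like
        family = paste0("Ped", p), parents = pairs[[p]],
        seed = derive_seed(seed, "ped", p)
      )
    })
    mixed <- mixed[!vapply(mixed, is.null, logical(1))]
  }
  geno <- bind_geno(c(fams, mixed))

  if (missing_rate > 0) {
    calls <- geno_calls(geno)
    drop <- with_seed(derive_seed(seed, "missing"), {
      which(runif(length(calls)) < missing_rate)
    })
    calls[drop] <- NA_real_
    geno <- geno_matrix(calls, marker_map(geno), line_info(geno))
  }

  arch <- purrr::imap(traits, function(tr, nm) {
    a <- sim_trait_architecture(
      map, n_qtl = tr$n_qtl, h2_target = tr$h2,
      pop_offsets = tr$pop_offsets, trait = nm,
      seed = derive_seed(seed, "arch", nm)
    )
    scale_arch_to_panel(a, geno)
  })

  truth <- purrr::imap(arch, function(a, nm) {
    mutate(genetic_values(geno, a), trait = nm)
  }) |> list_rbind()

  # mean kinship diagonal: converts line-to-line genetic variance to the
  # additive variance of the K-parameterised mixed model (about 2 for an
  # inbred panel), so h2_target is a *genomic* heritability
  mm <- impute_marker_means(geno)
  pp <- colMeans(mm + 1) / 2
  k_bar <- sum(sweep(mm, 2L, 2 * pp - 1)^2) /
    (nrow(mm) * 2 * sum(pp * (1 - pp)))

  pheno <- purrr::imap(arch, function(a, nm) {
    gv <- genetic_values(geno, a)
    sim_trials(
      gv, h2_target = a$h2_target,
      n_env = n_env, n_blocks = n_blocks, mu = traits[[nm]]$mu,
      gen_var = var(gv$g) / k_bar,
      trait = nm, seed = derive_seed(seed, "trials", nm)
    )
  }) |> list_rbind()

  structure(
    list(geno = geno, pheno = pheno, arch = arch, truth = truth,
         h2_target = vapply(arch, function(a) a$h2_target, numeric(1)),
         seed = seed),
    class = "gs_sim"
  )
}

#' Default trait settings for [sim_gs_dataset()]
#'
#' Three traits mirroring the study's panel: `protein` (high heritability,
#' Pop1 slightly below the rest), `oil` (high heritability with strong
#' divergence, Pop1 well above the rest), and `yield` (low heritability, no
#' population divergence). Offsets are in genetic-SD units; `mu` in trait
#' units.
#'
#' @return Named list of per-trait settings.
#' @export
default_trait_settings <- function() {
  list(
    protein = list(h2 = 0.8, n_qtl = 40, pop_offsets = c(Pop1 = -0.75), mu = 41),
    oil     = list(h2 = 0.8, n_qtl = 40, pop_offsets = c(Pop1 = 1.5),  mu = 21),
    yield   = list(h2 = 0.2, n_qtl = 40, pop_offsets = c(),            mu = 3500)
  )
}

#' @export
print.gs_sim <- function(x, ...) {
  cat("<gs_sim> simulated genomic-selection dataset\n")
  print(x$geno)
  cat(sprintf("traits: %s\n",
              paste(sprintf("%s (h2 %.2f)", names(x$h2_target), x$h2_target),
                    collapse = ", ")))
  cat(sprintf("%d plot records\n", nrow(x$pheno)))
  invisible(x)
}
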