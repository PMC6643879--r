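#' Assign a QTL architecture for a simulated trait
#'
#' Samples `n_qtl` markers from the map and gives each an additive
#' allele-substitution effect drawn from `effect_dist`. The architecture
#' also records the target genomic heritability used later to calibrate
#' residual variance, and optional per-population mean offsets (trait
#' units), which create between-population mean divergence on top of the
#' polygenic signal.
#'
#' @param map Genetic map tibble.
#' @param n_qtl Number of QTL (<= number of markers).
#' @param h2_target Target narrow-sense genomic heritability in `(0, 1)`.
#' @param effect_dist Function `f(n)` returning `n` additive effects;
#'   default standard normal.
#' @param pop_offsets Named numeric vector of population mean offsets in
#'   trait units; populations not named get 0.
#' @param trait Trait name.
#' @param seed Integer seed.
#' @return A `trait_arch`: list with `qtl` (tibble `marker`, `effect`),
#'   `h2_target`, `pop_offsets`, `trait`.
#' @export
sim_trait_architecture <- function(map, n_qtl, h2_target,
                                   effect_dist = stats::rnorm,
                                   pop_offsets = c(), trait = "trait",
                                   seed = 1L) {
  assert_scalar_prob(h2_target, "h2_target", open = TRUE)
  if (n_qtl > nrow(map)) abort("n_qtl exceeds the number of mapped markers")
  if (n_qtl == 0 && h2_target > 0) {
    abort("n_qtl = 0 is inconsistent with a positive h2_target")
  }
  qtl <- with_seed(derive_seed(seed, "qtl", trait), {
    idx <- sort(sample.int(nrow(map), n_qtl))
    tibble(marker = map$marker[idx], effect = effect_dist(n_qtl))
  })
  structure(
    list(qtl = qtl, h2_target = h2_target,
         pop_offsets = pop_offsets, trait = trait),
    class = "trait_arch"
  )
}

#' @export
print.trait_arch <- function(x, ...) {
  cat(sprintf("<trait_arch> '%s': %d QTL, target h2 = %.2f\n",
              x$trait, nrow(x$qtl), x$h2_target))
  if (length(x$pop_offsets)) {
    cat("population offsets:",
        paste(sprintf("%s %+0.2f", names(x$pop_offsets), x$pop_offsets),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' True genetic values of simulated lines
#'
#' `g_i = offset(population_i) + sum_k a_k x_ik` over the architecture's QTL,
#' with coded calls `x` in `{-1, 0, +1}` and missing QTL calls mean-imputed
#' per marker.
#'
#' @param geno A [geno_matrix()] containing all QTL markers.
#' @param arch A [sim_trait_architecture()] object.
#' @return A tibble `line`, `population`, `g`.
#' @export
genetic_values <- function(geno, arch) {
  missing_qtl <- setdiff(arch$qtl$marker, marker_map(geno)$marker)
  if (length(missing_qtl)) {
    abort(sprintf("QTL markers absent from genotypes: %s",
                  paste(head(missing_qtl, 5), collapse = ", ")))
  }
  m <- impute_marker_means(select_markers(geno, arch$qtl$marker))
  eff <- arch$qtl$effect[match(colnames(m), arch$qtl$marker)]
  li <- line_info(geno)
  off <- rep(0, nrow(li))
  if (length(arch$pop_offsets)) {
    hit <- match(li$population, names(arch$pop_offsets))
    off <- ifelse(is.na(hit), 0, arch$pop_offsets[hit])
  }
  tibble(line = li$line, population = li$population,
         g = as.numeric(m %*% eff) + off)
}

# rescale QTL effects so that Var(g) (offsets excluded) equals target_var on
# this panel; gives offsets a fixed meaning in genetic-SD units
scale_arch_to_panel <- function(arch, geno, target_var = 1) {
  no_off <- arch
  no_off$pop_offsets <- c()
  vg <- var(genetic_values(geno, no_off)$g)
  if (vg <= 0) abort("architecture has zero genetic variance on this panel")
  arch$qtl$effect <- arch$qtl$effect * sqrt(target_var / vg)
  arch
}
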