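#' Simulate multi-environment RCBD trials for a set of genetic values
#'
#' Generates plot-level phenotypes
#' `y_ijb = mu + g_i + E_j + (gE)_ij + S_l(j) + eps_ijb`
#' with independent normal environment, genotype-by-environment,
#' set-within-environment, and plot residual components, in a randomized
#' complete block design with `n_blocks` blocks per environment (every line
#' appears once per block). Lines are partitioned into `n_sets` sets within
#' each population (mirroring maturity sets); each line also carries a
#' days-to-maturity class drawn once per line.
#'
#' The plot residual variance is calibrated from the target heritability by
#' the delta rule at the genotype-mean level: with `J` environments and `B`
#' blocks, `Va/(Va + s2_gxe/J + s2_eps/(J*B)) = h2_target`, where `Va`
#' defaults to the empirical variance of `g`. Environment and set effects
#' are common to all lines in the same environment/set, so they do not
#' enter the line-mean ratio. When the target is a *genomic* heritability
#' in the kinship parameterisation (`h2 = s2_a/(s2_a + s2_e)` with
#' `K = WW'/c`), pass `gen_var = Var(g) / mean(diag(K))`: an inbred panel
#' has `mean(diag(K))` near 2 under the `c = 2*sum(p*(1-p))` denominator,
#' so the additive variance on the kinship scale is about half the
#' line-to-line genetic variance ([sim_gs_dataset()] does this).
#'
#' @param g Tibble `line`, `population`, `g` from [genetic_values()].
#' @param h2_target Target line-mean heritability in `(0, 1)`.
#' @param n_env Number of environments (year x location combinations).
#' @param n_blocks Blocks per environment.
#' @param n_sets Sets per population (set-within-environment stratum).
#' @param env_vc,gxe_vc,set_vc Variance components as multiples of the
#'   empirical `Var(g)`.
#' @param gen_var Additive variance used in the delta rule; defaults to
#'   the empirical `Var(g)` (see Details for the genomic-scale option).
#' @param mu Grand mean (trait units).
#' @param n_dtm_classes Number of days-to-maturity classes assigned to lines.
#' @param trait Trait name stored in the records.
#' @param seed Integer seed.
#' @return A tibble with columns `line`, `env`, `set`, `block`,
#'   `dtm_class`, `trait`, `value`.
#' @export
sim_trials <- function(g, h2_target, n_env = 4, n_blocks = 2, n_sets = 2,
                       env_vc = 3, gxe_vc = 0.2, set_vc = 0.25, mu = 0,
                       gen_var = NULL, n_dtm_classes = 3, trait = "trait",
                       seed = 1L) {
  assert_scalar_prob(h2_target, "h2_target", open = TRUE)
  if (any(c(env_vc, gxe_vc, set_vc) < 0)) abort("variance components must be >= 0")
  stopifnot(n_env >= 1, n_blocks >= 1, n_sets >= 1)
  vg <- var(g$g)
  va <- gen_var %||% vg
  s2_env <- env_vc * vg
  s2_gxe <- gxe_vc * vg
  s2_set <- set_vc * vg
  s2_eps <- n_env * n_blocks * (va * (1 - h2_target) / h2_target - s2_gxe / n_env)
  if (s2_eps <= 0) {
    abort("gxe_vc too large for h2_target: calibrated residual variance is non-positive")
  }
  n <- nrow(g)
  with_seed(derive_seed(seed, "trials", trait), {
    # one set and one maturity class per line, fixed across environments;
    # sets interleave lines across populations (a maturity-like stratum):
    # population-aligned sets would let the set effect absorb genuine
    # between-family genetic signal in the BLUP model
    set_of <- mutate(g, set = paste0("set", ((dplyr::row_number() - 1L) %% n_sets) + 1L))
    dtm <- sample.int(n_dtm_classes, n, replace = TRUE)
    env_ids <- sprintf("env%02d", seq_len(n_env))
    env_eff <- rnorm(n_env, 0, sqrt(s2_env))
    gxe <- matrix(rnorm(n * n_env, 0, sqrt(s2_gxe)), n, n_env)
    sets <- unique(set_of$set)
    set_eff <- matrix(rnorm(length(sets) * n_env, 0, sqrt(s2_set)),
                      length(sets), n_env, dimnames = list(sets, env_ids))
    recs <- tidyr::expand_grid(
      i = seq_len(n), j = seq_len(n_env), block = seq_len(n_blocks)
    )
    recs$value <- mu + g$g[recs$i] + env_eff[recs$j] +
      gxe[cbind(recs$i, recs$j)] +
      set_eff[cbind(match(set_of$set[recs$i], sets), recs$j)] +
      rnorm(nrow(recs), 0, sqrt(s2_eps))
    tibble(
      line = g$line[recs$i],
      env = env_ids[recs$j],
      set = set_of$set[recs$i],
      block = recs$block,
      dtm_class = paste0("dtm", dtm[recs$i]),
      trait = trait,
      value = recs$value
    )
  })
}
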