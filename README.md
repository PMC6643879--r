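# soygs

Genomic selection (GS) analysis for inbred-line breeding programs, built
around the workflow of a soybean program evaluating GS for seed yield,
protein, and oil: multi-environment trial records are condensed to one
BLUP per line, marker effects are fitted by RR-BLUP, and predictive
ability is measured by replicated cross-validation under the three designs
a breeder faces — across a mixed panel, within a bi-parental family, and
into a new family trained on everything else. A bi-parental RIL simulator
makes the whole analysis testable end to end without any external data.

## Who it is for, and what is inside

Plant breeders and quantitative geneticists who want a transparent,
scripted version of the standard GS evaluation stack:

* **Phenotypic BLUPs** — `fit_ranef_model()` / `gs_blups()`: all-random
  model (genotype, environment, G×E, set-within-environment, optional
  days-to-maturity class) fitted by EM-REML on Henderson's mixed-model
  equations, with monotone restricted likelihood.
* **Kinship and heritability** — `additive_kinship()` builds the
  VanRaden-type matrix `A = WW'/c`, `c = 2Σp(1−p)`;
  `spectral_reml()` / `gs_heritability()` fit
  `y ~ N(1μ, Kσ²ₐ + Iσ²ₑ)` by a spectral (EMMA-style) 1-D REML search and
  report `h² = σ²ₐ/(σ²ₐ+σ²ₑ)`.
* **Prediction** — `rrblup()` + `predict()` (marker route) and
  `gblup_predict()` (kinship route), algebraically identical;
  `run_gs_cv()` runs the EGSD / WP / AP cross-validation designs over
  training-size and marker-density sweeps, `prediction_accuracy()` turns
  r_MP into r_MG = r_MP/√h².
* **Marker QC and LD** — `marker_qc()` (het > 10%, missing > 80%,
  MAF < 0.05 removed), `pairwise_r2()`, greedy `tag_snps()` at r² ≥ 0.8,
  and `thin_marker_sets()` for the half/4th/8th tag densities.
* **Structure diagnostics** — `genotype_pca()` and
  `inflation_decomposition()`, which splits predictive ability into
  overall vs within-population correlations to expose inflation from
  between-family mean differences.
* **Reporting** — `anova_fisher_lsd()` groups replicate predictive
  abilities with Fisher's LSD; `run_gs_pipeline()` orchestrates
  simulate → QC → tags → BLUP → h² → CV → PCA → report with caching.
* **Simulator** — `sim_gs_dataset()`: four F5:7-like bi-parental RIL
  families (single-seed descent under a Haldane map, ~1.6% residual
  heterozygosity) plus mixed-pedigree advanced lines, soybean-like LD from
  ancestral-mosaic founders, and multi-environment RCBD phenotypes with
  G×E, calibrated to target genomic heritabilities.

Results come back as tibbles; fitted objects have `tidy()`/`glance()`
methods and result types have `autoplot()` methods.

## Worked example

```r
library(soygs)

sim <- sim_gs_dataset(family_size = 40, n_mixed = 40, n_founders = 20,
                      map = sim_genetic_map(n_chrom = 5, markers_per_chrom = 60),
                      seed = 42)
geno  <- marker_qc(sim$geno)
blups <- gs_blups(sim$pheno)
gs_heritability(blups, geno)
#> # A tibble: 3 × 8
#>   trait       n sigma2_a sigma2_e     mu delta    h2 boundary
#>   <chr>   <int>    <dbl>    <dbl>  <dbl> <dbl> <dbl> <lgl>
#> 1 oil       200    0.529    0.105   22.3 0.199 0.834 FALSE
#> 2 protein   200    0.316    0.137   39.8 0.432 0.698 FALSE
#> 3 yield     200    0.117    0.260 3502.  2.23  0.310 FALSE

cv <- run_gs_cv(geno, blups, "egsd", trait = "protein",
                n_train = c(50, 100, 150), vs_size = 30, n_reps = 25, seed = 7)
cv_summary(cv)
#> # A tibble: 3 × 8
#>   scheme trait   population marker_set n_train mean_r   sd_r n_reps
#> 1 egsd   protein <NA>       all             50  0.755 0.0668     25
#> 2 egsd   protein <NA>       all            100  0.821 0.0517     25
#> 3 egsd   protein <NA>       all            150  0.843 0.0561     25

anova_fisher_lsd(cv, "n_train")
#> <lsd_result> F(2, 72) = 15.28, p = 2.93e-06; LSD(0.05) = 0.033
#>   level     n  mean     sd group
#> 1 150      25 0.843 0.0561 a
#> 2 100      25 0.821 0.0517 a
#> 3 50       25 0.755 0.0668 b
```

Read: on this simulated panel the protein-like trait (target genomic
h² = 0.8, estimated 0.70 here) reaches a mean predictive ability of 0.84
at a training size of 150, and Fisher's LSD says 100 and 150 are
statistically equivalent while 50 lags — the training-size
diminishing-returns pattern. The yield-like trait (h² ≈ 0.2) predicts far
worse under every design; `autoplot(cv)` draws the sweep.

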