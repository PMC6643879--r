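---
title: "Genomic selection in an inbred breeding program: models, simulator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection in an inbred breeding program: models, simulator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

soygs evaluates genomic selection (GS) the way an applied soybean breeding
program would: phenotypic records from multi-environment yield trials are
condensed to one adjusted value per line (BLUPs), marker effects are fitted
by ridge-regression BLUP (RR-BLUP), and predictive ability is measured by
cross-validation under the three designs a breeder actually faces —
predicting across a mixed panel, within a bi-parental family, and into a
new family from everything else. This vignette explains the models, the
synthetic data the package tests itself on, and the choices made where the
design was genuinely open.

## The phenotypic model

Plot-level records from randomized complete block trials are fitted with an
all-random-effects model per trait,

$$y_{ijb} = \mu + g_i + E_j + (gE)_{ij} + S_{l(j)} + \varepsilon_{ijb},$$

with genotype, environment (year x location), genotype-by-environment
interaction, set-within-environment, and (for yield) a days-to-maturity
class, all independent normal. `fit_ranef_model()` maximizes the restricted
likelihood by EM iterations on Henderson's mixed-model equations. Two
numerical choices matter:

* **Absorption.** The factor with the most levels whose incidence
  crossproduct is diagonal — in these layouts the G-by-E interaction — is
  absorbed through its Schur complement, so each EM step factors only a
  system of the order of the genotype count. This is what keeps a
  ~500-line, ~4,000-plot fit in the tens of milliseconds per iteration.
* **Acceleration and convergence.** Plain EM is monotone but approaches
  small components sublinearly. Every third iteration the package attempts
  an Aitken extrapolation along the step direction and accepts it only if
  the restricted likelihood does not decrease, so the monotone-likelihood
  property (asserted in the tests) survives. Convergence is declared when
  the largest change in any component is below `tol = 1e-6` relative to
  that component, judging components smaller than 0.1% of the phenotypic
  variance on absolute change instead — a purely relative criterion never
  triggers for a component whose true value is zero.

Genotype BLUPs are reported with the grand mean added
(`genotype_blups(include_mean = TRUE)`); downstream correlations are
mean-invariant, but tables then read in trait units. Days-to-maturity
enters as a categorical random factor, the plainest reading of "a random
factor" for a class-like covariate; both decisions are configurable.

## Kinship, heritability, and the two prediction routes

The additive relationship matrix is VanRaden-type: with calls coded
$x \in \{-1, 0, +1\}$ and $p_k$ the frequency of the $+1$ allele,
$W_{ik} = x_{ik} + 1 - 2p_k$ and $A = WW'/c$, $c = 2\sum_k p_k(1-p_k)$.
Missing calls are mean-imputed per marker before centering, matching the
common A.mat default. Genomic heritability comes from the one-kinship
mixed model $y \sim N(1\mu,\; K\sigma^2_a + I\sigma^2_e)$, fitted by
`spectral_reml()`: the restricted likelihood is profiled down to the single
ratio $\delta = \sigma^2_e/\sigma^2_a$ on the spectrum of $K$ projected
orthogonally to the intercept, and optimized over
$\log\delta \in [-10, 10]$ by a 101-point bracket plus Brent search
(tolerance `1e-8`); hits on the search bounds are flagged rather than
silently returned. Then $h^2 = \sigma^2_a/(\sigma^2_a+\sigma^2_e)$.

One parameterisation point deserves emphasis. For a panel of (nearly)
inbred lines the diagonal of $A$ under the $c = 2\sum p(1-p)$ denominator
is close to 2, so $\sigma^2_a$ is about *half* the line-to-line genetic
variance, and the genomic $h^2$ above is correspondingly smaller than a
line-mean repeatability. The low yield heritabilities reported by
kin.blup-style analyses of inbred panels live in this convention, and so
does everything in this package — including the simulator, which
calibrates its residual against $\mathrm{Var}(g)/\overline{\mathrm{diag}(K)}$
so that `h2_target` means genomic heritability on exactly the scale the
estimator reports.

Prediction runs by either of two algebraically identical routes:
marker-effect RR-BLUP, $\hat u = W'(WW' + \lambda I)^{-1}(y - 1\hat\mu)$
with $\lambda = c\,\delta$, or kinship GBLUP,
$\hat g_{\text{test}} = K_{\text{test,train}}(K_{\text{train,train}} +
\delta I)^{-1}(y - 1\hat\mu)$. Their equality on shared centering
frequencies is the central algebraic test of the package (`<= 1e-8` on
random instances). The kinship is repaired to positive semi-definite only
when genuinely indefinite (eigenvalues below $-10^{-8}\lambda_{\max}$ are
floored), so Gram matrices pass through bit-exact and the duality is not
perturbed. The shrinkage ratio is refit inside every cross-validation
replicate from its own training set; no information flows from the
validation phenotypes.

## Cross-validation designs

`run_gs_cv()` implements the three designs with a shared skeleton: per
replicate a validation set (VS) and a disjoint training set (TS) are drawn,
RR-BLUP/GBLUP is refit on the TS, and the Pearson correlation between
predicted GEBVs and observed BLUPs in the VS is recorded ($r_{MP}$). The
summary is the mean of replicate correlations, not the correlation of
pooled predictions — replicate averaging is also what the per-line mean
GEBVs for the inflation diagnostic are built from. Replicate $i$ is seeded
`seed + i`, so the whole sweep is reproducible and two schemes at the same
seed draw the same validation sets.

* **EGSD** (entire dataset): VS of 50 from the whole panel, TS sizes
  50-400.
* **WP** (within population): VS of 20 and TS of 50 from one bi-parental
  family.
* **AP** (across populations): VS of 20 from the target family, TS drawn
  from the other lines after removing *all full sibs* of the target family
  (lines sharing the same unordered parent pair). The VS size of 20
  matches WP so the two schemes' replicate variances are comparable;
  whole-family validation is available via `vs_size`.

Prediction accuracy is reported as $r_{MG} = r_{MP}/\sqrt{h^2}$ when asked
for (`prediction_accuracy()`).

## The synthetic study

`sim_gs_dataset()` generates the panel every test runs on, shaped like a
late-maturity soybean GS dataset: four bi-parental F5:7-like RIL families
of 84 lines plus 150 advanced lines from 15 small mixed pedigrees; 20
chromosomes x 130 markers x 100 cM (Haldane map function, no
interference); three traits with 40 QTL each — two at genomic $h^2 = 0.8$
(the "protein" and "oil" analogs) and one at $h^2 = 0.2$ ("yield") — and
multi-environment RCBD trials (4 environments x 2 blocks) with G-by-E.
Key modelling decisions:

* **Single-seed descent.** Each RIL is advanced from the F1 by six selfing
  meioses carrying one offspring per generation; residual heterozygosity
  is retained, giving the F5:7-expected ~1.6% ($2^{-6}$) — verified
  against the closed form in the tests.
* **Founders as ancestral mosaics.** Founders are recombinant mosaics of 4
  ancestral haplotypes with ~40 cM segments, every marker polymorphic
  within the ancestral pool. This is the lever that produces soybean-like
  panel LD — roughly half the markers are redundant at $r^2 \ge 0.8$, so
  greedy tagging thins ~2,570 QC-passing markers to ~1,380 tags — and
  bi-parental family structure with PC1 around 11-12% of genotypic
  variance (PC2 ~9.5%, PC3 ~8%). Independent-founder sampling
  (`n_ancestors = 0`) is retained for calibration tests.
* **The "oil" divergence.** One high-$h^2$ trait gives Pop1 a mean offset
  of +1.5 genetic SD (and the protein analog -0.75), reproducing the
  situation where one family sits above the rest: whole-panel predictive
  ability is then partly between-family mean separation, which
  `inflation_decomposition()` makes visible as overall $r$ exceeding every
  within-family $r$.
* **Sets interleave families.** The set-within-environment stratum is
  assigned round-robin across the panel (a maturity-like grouping).
  Family-aligned sets would let the set effect absorb genuine
  between-family genetic signal in the BLUP model and bias $h^2$ downward.
* **Residual calibration.** Plot residual variance is solved from the
  target heritability at the genotype-mean level,
  $\sigma^2_\varepsilon = JB\,(V_a(1-h^2)/h^2 - \sigma^2_{gE}/J)$, with
  $V_a$ on the kinship scale as above. Environment, G-by-E, and set
  variances default to 3, 0.2, and 0.25 times the genetic variance.

What the generator does *not* emulate: selection during line advancement,
dominance or epistasis, genotyping batch effects, unbalanced or
incomplete trial designs, and maturity-driven confounding between sets and
genetics. Tests passing on this panel therefore demonstrate correctness of
the machinery and qualitative reproduction of the design phenomena
(heritability ordering, training-size gains with diminishing returns,
WP > AP, density robustness, structure inflation), not quantitative
agreement with any particular field dataset.

## Reporting

`anova_fisher_lsd()` compares replicate predictive abilities across levels
of a factor by one-way ANOVA (base `aov`) and groups levels with Fisher's
LSD at $\alpha = 0.05$:
$\mathrm{LSD} = t_{1-\alpha/2,\,df_e}\sqrt{2\,\mathrm{MSE}/n}$, harmonic
mean $n$ for unbalanced levels. Letters are assigned on the
descending-mean order by maximal intervals, which for a constant critical
difference is exactly consistent with the pairwise decisions (a property
the tests assert). Its type-I rate is calibrated under a simulated null.

## Problem sizes used in the checks

The automated checks run at sizes chosen to exercise the full default
panel while staying desk-scale: the design-reproduction properties use the
default 486-line, ~2,570-marker panel with 40-50 cross-validation
replicates per configuration; heritability recovery uses 50 independent
120-line RIL panels per target; the algebraic identities use 50 random
instances of 12-30 lines; the ANOVA null calibration uses 500 simulated
datasets. The pipeline itself defaults to the study's 100 replicates.

## Known limitations

* EM-REML, even accelerated, is not competitive with average-information
  REML on large multi-trait problems; it was chosen for its monotonicity
  and robustness at this package's scale.
* The spectral REML fits a single kinship; environment-specific genetic
  variances (h^2 per year) are out of scope.
* `pairwise_r2()` treats near-inbred lines as haplotypes by dropping
  heterozygous calls pairwise; it is not a phased-haplotype $r^2$ and will
  differ on panels with substantial heterozygosity.
* The ">80% missing" QC default is deliberately permissive (array panels
  of inbreds); tighten `max_missing` for sparser genotyping platforms.
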