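#' Tidy variance components of a spectral REML fit
#'
#' @param x A `gs_reml` object from [spectral_reml()].
#' @param ... Unused.
#' @return A tibble `term`, `estimate`.
#' @export
tidy.gs_reml <- function(x, ...) {
  tibble(term = c("sigma2_a", "sigma2_e", "mu"),
         estimate = c(x$sigma2_a, x$sigma2_e, x$mu))
}

#' @rdname tidy.gs_reml
#' @export
glance.gs_reml <- function(x, ...) {
  tibble(h2 = x$h2, delta = x$delta, logLik = x$loglik, n = x$n,
         boundary = x$boundary)
}

#' Tidy marker effects of an RR-BLUP fit
#'
#' @param x An `rrblup_fit` from [rrblup()].
#' @param ... Unused.
#' @return Tibble `marker`, `effect`.
#' @export
tidy.rrblup_fit <- function(x, ...) x$effects

#' @rdname tidy.rrblup_fit
#' @export
glance.rrblup_fit <- function(x, ...) {
  tibble(mu = x$mu, lambda = x$lambda, delta = x$delta, h2 = x$vc$h2,
         n_markers = nrow(x$effects))
}

#' Tidy variance components of a multi-factor EM-REML fit
#'
#' @param x A `ranef_fit` from [fit_ranef_model()].
#' @param ... Unused.
#' @return Tibble `term`, `variance`.
#' @export
tidy.ranef_fit <- function(x, ...) x$vc

#' @rdname tidy.ranef_fit
#' @export
glance.ranef_fit <- function(x, ...) {
  tibble(mu = x$mu, logLik = x$loglik[length(x$loglik)],
         n_iter = x$n_iter, converged = x$converged, nobs = x$n)
}

#' Tidy a Fisher's-LSD comparison
#'
#' @param x An `lsd_result` from [anova_fisher_lsd()].
#' @param ... Unused.
#' @return The letter-group tibble (`level`, `n`, `mean`, `sd`, `group`).
#' @export
tidy.lsd_result <- function(x, ...) x$groups

#' @rdname tidy.lsd_result
#' @export
glance.lsd_result <- function(x, ...) {
  tibble(statistic = x$anova$statistic[1], p.value = x$anova$p.value[1],
         df = x$anova$df[1], df.residual = x$anova$df[2], lsd = x$lsd,
         alpha = x$alpha)
}

#' Tidy the variance-explained table of a genotype PCA
#'
#' @param x A `gs_pca` from [genotype_pca()].
#' @param ... Unused.
#' @return Tibble `component`, `pct`.
#' @export
tidy.gs_pca <- function(x, ...) x$var_explained

#' @rdname tidy.gs_pca
#' @export
augment.gs_pca <- function(x, ...) x$scores
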