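#' Spectral REML for the single-kinship mixed model
#'
#' Fits `y = 1*mu + g + e`, `g ~ N(0, K sigma2_a)`, `e ~ N(0, I sigma2_e)`
#' by restricted maximum likelihood, profiling everything down to the single
#' variance ratio `delta = sigma2_e / sigma2_a`. The restricted likelihood
#' is evaluated on the spectrum of `K` projected orthogonally to the
#' intercept, so each candidate `delta` costs O(n); the optimum over
#' `log(delta)` is found by a coarse grid bracket followed by Brent search.
#' This is the efficient mixed-model (EMMA-style) computation used for
#' genomic heritability.
#'
#' @param y Numeric vector of one adjusted phenotype (BLUP) per line, or a
#'   tibble with columns `line` and `blup` (aligned to `K` by name).
#' @param K A [additive_kinship()] matrix (or any symmetric PSD matrix)
#'   over the same lines.
#' @param bounds Search bounds for `log(delta)`.
#' @param tol Brent tolerance on `log(delta)`.
#' @return A `gs_reml` object: list with `sigma2_a`, `sigma2_e`, `mu`,
#'   `delta`, `h2`, `loglik` (restricted, all constants included),
#'   `boundary` (TRUE if the optimum pinned at a search bound), `n`.
#' @export
spectral_reml <- function(y, K, bounds = c(-10, 10), tol = 1e-8) {
  if (is.data.frame(y)) {
    stopifnot(all(c("line", "blup") %in% names(y)))
    yv <- setNames(y$blup, y$line)
  } else {
    yv <- y
  }
  K <- kinship_matrix(K)
  if (!is.null(names(yv)) && !is.null(rownames(K))) {
    if (!all(names(yv) %in% rownames(K))) {
      abort("some lines in `y` are missing from the kinship matrix")
    }
    K <- K[names(yv), names(yv)]
  }
  n <- length(yv)
  if (n < 3) abort("spectral REML needs at least 3 lines")
  if (n != nrow(K)) abort("length(y) must match dim(K)")
  if (var(yv) == 0) abort("phenotype has zero variance: variance ratio undefined")

  # spectrum of K on the orthogonal complement of the intercept
  s_ks <- K - outer(rowMeans(K), rep(1, n)) -
    outer(rep(1, n), colMeans(K)) + mean(K)
  es <- eigen((s_ks + t(s_ks)) / 2, symmetric = TRUE)
  xi <- es$values[seq_len(n - 1)]
  xi <- pmax(xi, 0)
  eta <- as.numeric(crossprod(es$vectors[, seq_len(n - 1)], yv - mean(yv)))

  # profiled restricted log-likelihood (constants kept so it matches a
  # dense evaluation of the REML criterion exactly)
  rll <- function(log_delta) {
    d <- exp(log_delta)
    # floor keeps the criterion finite when y lies exactly in the range of
    # the kinship factor (noiseless limit)
    ypy <- max(sum(eta^2 / (xi + d)), 1e-300)
    -0.5 * ((n - 1) * log(ypy / (n - 1)) + sum(log(xi + d)) + log(n) +
              (n - 1) * (1 + log(2 * pi)))
  }
  grid <- seq(bounds[1], bounds[2], length.out = 101)
  vals <- vapply(grid, rll, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(rll, c(lo, hi), maximum = TRUE, tol = tol)
  log_delta <- opt$maximum
  boundary <- log_delta <= bounds[1] + 1e-3 || log_delta >= bounds[2] - 1e-3

  delta <- exp(log_delta)
  sigma2_a <- sum(eta^2 / (xi + delta)) / (n - 1)
  sigma2_e <- delta * sigma2_a
  hinv_1 <- solve(K + delta * diag(n), rep(1, n))
  mu <- sum(hinv_1 * yv) / sum(hinv_1)
  structure(
    list(sigma2_a = sigma2_a, sigma2_e = sigma2_e, mu = mu, delta = delta,
         h2 = 1 / (1 + delta), loglik = opt$objective, boundary = boundary,
         n = n),
    class = "gs_reml"
  )
}

#' @export
print.gs_reml <- function(x, ...) {
  cat(sprintf(
    "<gs_reml> n = %d: sigma2_a = %.4g, sigma2_e = %.4g, h2 = %.3f%s\n",
    x$n, x$sigma2_a, x$sigma2_e, x$h2,
    if (x$boundary) " [boundary]" else ""
  ))
  invisible(x)
}

#' Genomic heritability from variance components
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_e)`.
#'
#' @param sigma2_a Additive genetic variance (or a `gs_reml` fit, in which
#'   case `sigma2_e` is ignored).
#' @param sigma2_e Error variance.
#' @return Heritability in `[0, 1]`.
#' @export
#' @examples
#' genomic_heritability(0.82, 0.18)
genomic_heritability <- function(sigma2_a, sigma2_e = NULL) {
  if (inherits(sigma2_a, "gs_reml")) {
    fit <- sigma2_a
    sigma2_a <- fit$sigma2_a
    sigma2_e <- fit$sigma2_e
  }
  if (sigma2_a < 0 || sigma2_e < 0) abort("variance components must be >= 0")
  if (sigma2_a + sigma2_e <= 0) abort("both variance components are zero: h2 undefined")
  sigma2_a / (sigma2_a + sigma2_e)
}

#' Genomic heritability of each trait in a BLUP table
#'
#' Builds the additive kinship once and runs [spectral_reml()] per trait.
#'
#' @param blups Tibble `line`, `trait`, `blup`.
#' @param geno A QC-filtered [geno_matrix()] covering the lines.
#' @param K Optional precomputed [additive_kinship()].
#' @return A tibble: `trait`, `n`, `sigma2_a`, `sigma2_e`, `mu`, `delta`,
#'   `h2`, `boundary`.
#' @export
gs_heritability <- function(blups, geno = NULL, K = NULL) {
  if (is.null(K)) {
    if (is.null(geno)) abort("supply either `geno` or a precomputed `K`")
    K <- additive_kinship(geno)
  }
  blups |>
    dplyr::group_split(.data$trait) |>
    purrr::map(function(d) {
      fit <- spectral_reml(d, K)
      tibble(trait = d$trait[1], n = fit$n, sigma2_a = fit$sigma2_a,
             sigma2_e = fit$sigma2_e, mu = fit$mu, delta = fit$delta,
             h2 = fit$h2, boundary = fit$boundary)
    }) |>
    list_rbind()
}
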