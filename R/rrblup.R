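#' Fit RR-BLUP marker effects
#'
#' Ridge-regression BLUP of all marker effects jointly:
#' `y = 1*mu + W u + e`, `u ~ N(0, I sigma2_u)`, with `W` the centered coded
#' marker matrix (`W_ik = x_ik + 1 - 2 p_k`). The ridge parameter
#' `lambda = sigma2_e / sigma2_u` is obtained by [spectral_reml()] on the
#' marker-derived kinship `K = W W' / c` of the training lines (so
#' `lambda = c * delta`), and effects are recovered through the kernel
#' identity `u_hat = W'(W W' + lambda I)^-1 (y - mu_hat)`, which equals the
#' primal ridge solution `(W'W + lambda I)^-1 W'(y - mu_hat)`.
#'
#' @param y Numeric vector of adjusted phenotypes (one per training line),
#'   or a tibble `line`, `blup`.
#' @param geno Training [geno_matrix()] (missing calls mean-imputed).
#' @param p Optional centering allele frequencies shared with a prediction
#'   set; defaults to training-panel frequencies.
#' @return An `rrblup_fit`: `mu`, `effects` (tibble `marker`, `effect`),
#'   `lambda`, `delta`, `c`, `p`, `vc` (the `gs_reml` fit), `markers`.
#' @export
rrblup <- function(y, geno, p = NULL) {
  if (is.data.frame(y)) {
    stopifnot(all(c("line", "blup") %in% names(y)))
    geno <- geno[y$line, ]
    y <- setNames(y$blup, y$line)
  }
  if (length(y) != nrow(geno)) abort("one phenotype per training line required")
  if (length(y) < 2) abort("at least 2 training lines required")
  if (sd(y) == 0) {
    # no phenotypic variation: every effect shrinks to zero
    p0 <- p %||% marker_stats(geno)$p
    vc0 <- structure(list(sigma2_a = 0, sigma2_e = 0, mu = y[[1]],
                          delta = Inf, h2 = 0, loglik = NA_real_,
                          boundary = TRUE, n = length(y)),
                     class = "gs_reml")
    return(structure(
      list(mu = y[[1]], effects = tibble(marker = colnames(geno), effect = 0),
           lambda = Inf, delta = Inf, c = 2 * sum(p0 * (1 - p0)), p = p0,
           vc = vc0, markers = colnames(geno)),
      class = "rrblup_fit"
    ))
  }
  K <- additive_kinship(geno, p = p)
  p <- attr(K, "p")
  cc <- attr(K, "c")
  vc <- spectral_reml(y, K)
  m <- impute_marker_means(geno)
  w <- sweep(m, 2L, 2 * p - 1)
  if (all(apply(w, 2, sd) == 0)) abort("zero marker variance in training set")
  # (WW' + lambda I) = c (K + delta I)
  alpha <- solve(kinship_matrix(K) + vc$delta * diag(length(y)), y - vc$mu) / cc
  u_hat <- as.numeric(crossprod(w, alpha))
  structure(
    list(mu = vc$mu, effects = tibble(marker = colnames(geno), effect = u_hat),
         lambda = cc * vc$delta, delta = vc$delta, c = cc, p = p, vc = vc,
         markers = colnames(geno)),
    class = "rrblup_fit"
  )
}

#' @export
print.rrblup_fit <- function(x, ...) {
  cat(sprintf("<rrblup_fit> %d markers, mu = %.4g, lambda = %.4g (h2 = %.3f)\n",
              nrow(x$effects), x$mu, x$lambda, x$vc$h2))
  invisible(x)
}

#' Predict genomic estimated breeding values from marker effects
#'
#' `GEBV_i = mu_hat + sum_k u_hat_k w_ik`, with the prediction genotypes
#' centered by the training-set allele frequencies (missing calls are
#' imputed at the training mean, contributing zero).
#'
#' @param object An [rrblup()] fit.
#' @param geno A [geno_matrix()] containing all training markers.
#' @param ... Unused.
#' @return A tibble `line`, `population`, `gebv`.
#' @export
predict.rrblup_fit <- function(object, geno, ...) {
  missing_ids <- setdiff(object$markers, marker_map(geno)$marker)
  if (length(missing_ids)) {
    abort(sprintf(
      "prediction genotypes lack %d training marker(s): %s",
      length(missing_ids), paste(head(missing_ids, 5), collapse = ", ")
    ))
  }
  g <- select_markers(geno, object$markers)
  m <- geno_calls(g)
  ord <- match(object$markers, colnames(m))
  m <- m[, ord, drop = FALSE]
  w <- sweep(m, 2L, 2 * object$p - 1)
  w[is.na(w)] <- 0
  li <- line_info(g)
  tibble(line = li$line, population = li$population,
         gebv = object$mu + as.numeric(w %*% object$effects$effect))
}

#' Kinship-route GBLUP prediction
#'
#' BLUP of unobserved genetic values given training phenotypes under
#' `y = 1*mu + g + e`, `g ~ N(0, K sigma2_a)`:
#' `g_hat_test = K[test, train] (K[train, train] + delta I)^-1 (y - 1*mu_hat)`,
#' with `delta` estimated by [spectral_reml()] on the training block unless
#' supplied. Algebraically identical to the marker-effect route when `K` is
#' the marker-derived kinship with shared centering.
#'
#' @param y Named numeric vector of training phenotypes, or tibble `line`,
#'   `blup` (names must appear in `K`).
#' @param K Kinship over training and test lines.
#' @param test_ids Line ids to predict.
#' @param delta Optional fixed variance ratio `sigma2_e / sigma2_a`.
#' @return A tibble `line`, `gebv`.
#' @export
gblup_predict <- function(y, K, test_ids, delta = NULL) {
  if (is.data.frame(y)) y <- setNames(y$blup, y$line)
  if (is.null(names(y))) abort("training phenotypes must be named by line id")
  Km <- kinship_matrix(K)
  train_ids <- names(y)
  missing_ids <- setdiff(c(train_ids, test_ids), rownames(Km))
  if (length(missing_ids)) {
    abort(sprintf("kinship does not cover: %s",
                  paste(head(missing_ids, 5), collapse = ", ")))
  }
  Ktt <- Km[train_ids, train_ids]
  if (is.null(delta)) {
    fit <- spectral_reml(y, Ktt)
    delta <- fit$delta
    mu <- fit$mu
  } else {
    hinv_1 <- solve(Ktt + delta * diag(length(y)), rep(1, length(y)))
    mu <- sum(hinv_1 * y) / sum(hinv_1)
  }
  h <- Ktt + delta * diag(length(y))
  alpha <- tryCatch(solve(h, y - mu),
                    error = function(e) abort("singular GBLUP system"))
  g_hat <- as.numeric(Km[test_ids, train_ids, drop = FALSE] %*% alpha)
  tibble(line = test_ids, gebv = mu + g_hat)
}
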