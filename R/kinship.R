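#' Additive genomic relationship matrix
#'
#' VanRaden-style kinship from coded calls: with `x` in `{-1, 0, +1}` and
#' `p_k` the frequency of the `+1` allele, the centered matrix is
#' `W_ik = x_ik + 1 - 2 p_k` and `A = W W' / c` with
#' `c = 2 * sum_k p_k (1 - p_k)`. Missing calls are mean-imputed per marker
#' before centering. The result is made positive semi-definite by flooring
#' eigenvalues at `psd_floor * max(eigenvalue)` when needed.
#'
#' @param geno A QC-filtered [geno_matrix()].
#' @param p Optional centering frequencies (one per marker); defaults to
#'   frequencies computed from `geno` itself.
#' @param psd_floor Relative eigenvalue floor for the PSD repair.
#' @return A `kinship` object: the symmetric matrix with attributes `p`
#'   (centering frequencies) and `c` (denominator).
#' @export
additive_kinship <- function(geno, p = NULL, psd_floor = 1e-8) {
  m <- impute_marker_means(geno)
  if (is.null(p)) p <- colMeans(m + 1) / 2
  if (length(p) != ncol(m)) abort("`p` must supply one frequency per marker")
  cc <- 2 * sum(p * (1 - p))
  if (cc <= 0) abort("all markers monomorphic: kinship denominator is zero")
  w <- sweep(m, 2L, 2 * p - 1)
  a <- tcrossprod(w) / cc
  a <- (a + t(a)) / 2
  ev <- eigen(a, symmetric = TRUE)
  if (min(ev$values) < -psd_floor * max(ev$values)) {
    # genuinely indefinite (beyond Gram-matrix roundoff): floor eigenvalues
    vals <- pmax(ev$values, psd_floor * max(ev$values))
    a <- ev$vectors %*% (vals * t(ev$vectors))
    a <- (a + t(a)) / 2
    dimnames(a) <- list(rownames(m), rownames(m))
  }
  structure(a, p = p, c = cc, class = c("kinship", "matrix", "array"))
}

#' @export
print.kinship <- function(x, ...) {
  cat(sprintf("<kinship> %d x %d additive relationship matrix (c = %.3f)\n",
              nrow(x), ncol(x), attr(x, "c")))
  invisible(x)
}

# plain matrix view
kinship_matrix <- function(k) {
  m <- unclass(k)
  attr(m, "p") <- NULL
  attr(m, "c") <- NULL
  m
}
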