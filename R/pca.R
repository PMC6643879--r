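#' Principal component analysis of a genotype matrix
#'
#' Eigen-decomposition of the covariance of column-centered coded calls
#' (mean-imputed; not variance-standardized by default, so common variants
#' weigh more, the usual genotype-PCA convention). Components are oriented
#' so the largest-magnitude marker loading is positive; variance explained
#' is each eigenvalue's share of the total, summing to 100% over all
#' components.
#'
#' @param geno A QC-filtered [geno_matrix()] with >= 3 lines.
#' @param n_pc Number of score columns to return.
#' @param standardize Scale markers to unit variance before decomposition.
#' @return A `gs_pca`: list with `scores` (tibble `line`, `population`,
#'   `PC1`, ...) and `var_explained` (tibble `component`, `pct`, over all
#'   components).
#' @export
genotype_pca <- function(geno, n_pc = 10, standardize = FALSE) {
  if (nrow(geno) < 3) abort("PCA needs at least 3 lines")
  m <- impute_marker_means(geno)
  m <- scale(m, center = TRUE, scale = standardize)
  if (standardize) m[, attr(m, "scaled:scale") == 0] <- 0
  if (all(abs(m) < 1e-12)) abort("constant genotype matrix: PCA undefined")
  sv <- svd(m)
  ev <- sv$d^2
  n_pc <- min(n_pc, sum(ev > 0))
  scores <- sv$u[, seq_len(n_pc), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pc)], n_pc)
  # orient: largest-magnitude loading positive
  for (j in seq_len(n_pc)) {
    l <- sv$v[, j]
    if (l[which.max(abs(l))] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(n_pc))
  li <- line_info(geno)
  structure(
    list(
      scores = dplyr::bind_cols(tibble(line = li$line, population = li$population),
                                as_tibble(scores)),
      var_explained = tibble(component = seq_along(ev),
                             pct = 100 * ev / sum(ev))
    ),
    class = "gs_pca"
  )
}

#' @export
print.gs_pca <- function(x, ...) {
  top <- head(x$var_explained$pct, 3)
  cat(sprintf("<gs_pca> %d lines; PC1-3 explain %s%% of variance\n",
              nrow(x$scores), paste(sprintf("%.1f", top), collapse = "/")))
  invisible(x)
}

#' Decompose predictive ability into overall and within-population parts
#'
#' Correlates per-line mean predicted GEBVs with observed BLUPs overall and
#' separately within each population. When population means differ, the
#' overall correlation exceeds the typical within-population correlation:
#' between-population mean separation inflates apparent predictive ability
#' even when within-family signal is weak. The `gap` attribute (overall
#' minus mean within-population r) quantifies that inflation.
#'
#' @param df Tibble with columns `line`, `population`, `mean_gebv` (e.g.
#'   from [cv_per_line()]) and `blup` — or pass `blups` to join it in.
#' @param blups Optional tibble `line`, `blup` merged onto `df`.
#' @param marker_set Label carried into the report.
#' @param min_n Populations with fewer lines are skipped with a warning.
#' @return An `inflation_report` tibble: rows `overall` plus one per
#'   population with `n` and `r`; attributes `gap` and `data` (the joined
#'   per-line table, used by [autoplot.inflation_report()]).
#' @export
inflation_decomposition <- function(df, blups = NULL, marker_set = NA_character_,
                                    min_n = 3) {
  if (!is.null(blups)) {
    df <- left_join(df, select(blups, "line", "blup"), by = "line")
  }
  stopifnot(all(c("line", "population", "mean_gebv", "blup") %in% names(df)))
  if (anyNA(df$blup) || anyNA(df$mean_gebv)) {
    abort("every line needs both a mean GEBV and a BLUP")
  }
  pops <- split(df, df$population)
  small <- names(pops)[vapply(pops, nrow, integer(1)) < min_n]
  if (length(small)) {
    warn(sprintf("skipping population(s) with < %d lines: %s", min_n,
                 paste(small, collapse = ", ")))
    pops <- pops[!names(pops) %in% small]
  }
  within <- purrr::imap(pops, function(d, nm) {
    tibble(population = nm, n = nrow(d),
           r = predictive_ability(d$mean_gebv, d$blup))
  }) |> list_rbind()
  out <- bind_rows(
    tibble(population = "overall", n = nrow(df),
           r = predictive_ability(df$mean_gebv, df$blup)),
    within
  )
  out$marker_set <- marker_set
  attr(out, "gap") <- out$r[1] - mean(within$r)
  attr(out, "data") <- df
  class(out) <- c("inflation_report", class(out))
  out
}
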