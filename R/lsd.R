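#' One-way ANOVA with Fisher's LSD grouping of replicate predictive abilities
#'
#' Tests whether mean predictive ability differs across levels of a factor
#' (training-set size, marker density, ...) using the replicate `r` values
#' as observations, then groups levels by Fisher's least significant
#' difference at `alpha`:
#' `LSD = t(1 - alpha/2, df_error) * sqrt(2 * MSE / n)`,
#' with the harmonic mean of the level sizes as `n` when levels are
#' unbalanced. Letters are assigned by descending mean with standard
#' chaining: levels whose means differ by less than the LSD share a letter.
#'
#' @param cv Tibble of replicate results (e.g. a `gs_cv`), with the
#'   response in `response` and the grouping factor in `factor_name`.
#' @param factor_name Column to compare levels of (e.g. `"n_train"`,
#'   `"marker_set"`).
#' @param response Response column (default `"r"`).
#' @param alpha Significance level.
#' @return An `lsd_result`: `anova` (tibble `term`, `df`, `sumsq`,
#'   `meansq`, `statistic`, `p.value`), `lsd`, `alpha`, and `groups`
#'   (tibble `level`, `n`, `mean`, `sd`, `group`), ordered by descending
#'   mean.
#' @export
anova_fisher_lsd <- function(cv, factor_name, response = "r", alpha = 0.05) {
  assert_scalar_prob(alpha, "alpha", open = TRUE)
  d <- tibble(y = cv[[response]], lev = factor(cv[[factor_name]]))
  if (anyNA(d$y)) d <- filter(d, !is.na(.data$y))
  if (nlevels(droplevels(d$lev)) < 2) abort("need >= 2 factor levels")
  d$lev <- droplevels(d$lev)
  if (any(table(d$lev) < 2)) abort("need >= 2 replicates per level")
  fit <- aov(y ~ lev, data = d)
  an <- summary(fit)[[1]]
  df_err <- an["Residuals", "Df"]
  if (df_err <= 0) abort("zero error degrees of freedom")
  mse <- an["Residuals", "Mean Sq"]
  stats_tbl <- d |>
    group_by(.data$lev) |>
    summarise(n = dplyr::n(), mean = mean(.data$y), sd = sd(.data$y)) |>
    arrange(dplyr::desc(.data$mean))
  n_h <- nlevels(d$lev) / sum(1 / stats_tbl$n)  # harmonic mean level size
  lsd <- qt(1 - alpha / 2, df_err) * sqrt(2 * mse / n_h)

  # chaining on means sorted descending: for a constant critical difference
  # mutual non-significance is an interval property, so maximal intervals
  # [i, j] with mean_i - mean_j <= LSD get one letter each
  k <- nrow(stats_tbl)
  ends <- vapply(seq_len(k), function(i) {
    max(which(stats_tbl$mean[i] - stats_tbl$mean <= lsd + 1e-12))
  }, integer(1))
  # `ends` is non-decreasing, so [i, ends[i]] is maximal iff it reaches
  # further than its predecessor
  starts <- which(ends > c(-1L, ends[-k]))
  letters_vec <- character(k)
  for (i in seq_along(starts)) {
    rng <- starts[i]:ends[starts[i]]
    letters_vec[rng] <- paste0(letters_vec[rng], letters[i])
  }
  structure(
    list(
      anova = tibble(
        term = c(factor_name, "residuals"),
        df = an$Df, sumsq = an$`Sum Sq`, meansq = an$`Mean Sq`,
        statistic = an$`F value`, p.value = an$`Pr(>F)`
      ),
      lsd = lsd, alpha = alpha,
      groups = tibble(level = as.character(stats_tbl$lev), n = stats_tbl$n,
                      mean = stats_tbl$mean, sd = stats_tbl$sd,
                      group = letters_vec)
    ),
    class = "lsd_result"
  )
}

#' @export
print.lsd_result <- function(x, ...) {
  cat(sprintf("<lsd_result> F(%d, %d) = %.2f, p = %.3g; LSD(%.2g) = %.4g\n",
              x$anova$df[1], x$anova$df[2], x$anova$statistic[1],
              x$anova$p.value[1], x$alpha, x$lsd))
  print(x$groups)
  invisible(x)
}
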