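#' Predictive ability: correlation of GEBVs with observed BLUPs
#'
#' @param gebv,observed Paired numeric vectors (>= 3 finite pairs, both
#'   with non-zero variance).
#' @return Pearson product-moment correlation.
#' @export
predictive_ability <- function(gebv, observed) {
  ok <- is.finite(gebv) & is.finite(observed)
  if (sum(ok) < 3) abort("need at least 3 paired finite values")
  if (sd(gebv[ok]) == 0 || sd(observed[ok]) == 0) {
    abort("zero variance on one side: correlation undefined")
  }
  cor(gebv[ok], observed[ok])
}

#' Prediction accuracy from predictive ability and heritability
#'
#' `r_MG = r_MP / sqrt(h2)`: rescales the GEBV-phenotype correlation to an
#' estimate of the GEBV-genotypic-value correlation.
#'
#' @param r_mp Predictive ability.
#' @param h2 Heritability in `(0, 1]`.
#' @return Prediction accuracy.
#' @export
#' @examples
#' prediction_accuracy(0.81, 0.82)  # ~0.89
prediction_accuracy <- function(r_mp, h2) {
  if (any(h2 <= 0) || any(h2 > 1)) abort("h2 must lie in (0, 1]")
  r_mp / sqrt(h2)
}

# full-sib lines of a family: identical unordered parent pair
fullsib_lines <- function(line_tbl, population) {
  fam <- filter(line_tbl, .data$population == !!population)
  pr <- sort(c(fam$parent1[1], fam$parent2[1]))
  if (anyNA(pr)) return(fam$line)
  sib <- line_tbl$line[
    !is.na(line_tbl$parent1) & !is.na(line_tbl$parent2) &
      pmin(line_tbl$parent1, line_tbl$parent2) == pr[1] &
      pmax(line_tbl$parent1, line_tbl$parent2) == pr[2]
  ]
  union(fam$line, sib)
}

#' Replicated cross-validation of genomic prediction
#'
#' Runs one of the three designs for estimating predictive ability:
#'
#' * `"egsd"` — whole-dataset: validation set (default 50 lines) and
#'   training set drawn at random from the entire panel, disjoint.
#' * `"wp"` — within-population: both sets drawn from one bi-parental
#'   family (default VS 20, TS 50); full-sibs predict full-sibs.
#' * `"ap"` — across-population: VS drawn from the target family, TS from
#'   the remaining lines after removing all full-sibs of the target family
#'   (lines sharing both parents).
#'
#' Each replicate redraws both sets, refits the shrinkage parameter on its
#' own training set (kinship-route GBLUP, algebraically identical to
#' RR-BLUP), and records the Pearson correlation between predicted GEBVs
#' and observed BLUPs in the validation set. The summary `r_MP` is the mean
#' of the replicate correlations. Replicate `i` is seeded `seed + i`.
#'
#' @param geno QC-filtered [geno_matrix()] (restrict markers first with
#'   [select_markers()] to test a density).
#' @param blups Tibble `line`, `trait`, `blup` (one trait, or use `trait`).
#' @param scheme `"egsd"`, `"wp"`, or `"ap"`.
#' @param trait Trait to use when `blups` holds several.
#' @param population Target family (required for `"wp"` and `"ap"`).
#' @param n_train Training-set sizes to sweep.
#' @param vs_size Validation-set size (default 50 for EGSD, 20 otherwise).
#' @param n_reps Replicates per configuration.
#' @param marker_set Label stored in the results (e.g. `"all"`).
#' @param K Optional precomputed [additive_kinship()] of `geno`.
#' @param seed Master seed.
#' @return A `gs_cv` tibble: one row per replicate with `scheme`, `trait`,
#'   `population`, `marker_set`, `n_train`, `rep`, `r`. Attribute
#'   `per_line` holds each line's mean predicted GEBV across the replicates
#'   in which it fell in the validation set (used by
#'   [inflation_decomposition()]).
#' @export
run_gs_cv <- function(geno, blups, scheme = c("egsd", "wp", "ap"),
                      trait = NULL, population = NULL,
                      n_train = 50, vs_size = NULL, n_reps = 100,
                      marker_set = "all", K = NULL, seed = 1L) {
  scheme <- match.arg(scheme)
  if (!is.null(trait)) blups <- filter(blups, .data$trait == !!trait)
  trait_name <- trait %||% unique(blups$trait) %||% NA_character_
  if (length(unique(blups$trait)) > 1) abort("`blups` holds several traits; pass `trait`")
  vs_size <- vs_size %||% if (scheme == "egsd") 50L else 20L
  li <- line_info(geno)
  blups <- filter(blups, .data$line %in% li$line)
  yv <- setNames(blups$blup, blups$line)
  avail <- names(yv)
  if (is.null(K)) K <- additive_kinship(geno)

  if (scheme %in% c("wp", "ap")) {
    if (is.null(population)) abort("`population` is required for WP/AP schemes")
    fam <- intersect(avail, li$line[li$population == population])
    if (scheme == "wp" && length(fam) < vs_size + max(n_train)) {
      abort(sprintf("family %s has %d phenotyped lines; needs >= %d (VS %d + TS %d)",
                    population, length(fam), vs_size + max(n_train), vs_size,
                    max(n_train)))
    }
    pool <- setdiff(avail, fullsib_lines(li, population))
    if (scheme == "ap" && length(pool) < max(n_train)) {
      abort(sprintf(
        "after excluding full-sibs of %s the pool has %d lines; max feasible n_train is %d",
        population, length(pool), length(pool)))
    }
  } else {
    if (length(avail) < vs_size + max(n_train)) {
      abort(sprintf("panel has %d phenotyped lines; needs >= %d (VS %d + max TS %d)",
                    length(avail), vs_size + max(n_train), vs_size, max(n_train)))
    }
  }

  pred_sum <- setNames(numeric(length(avail)), avail)
  pred_n <- setNames(integer(length(avail)), avail)
  out <- vector("list", length(n_train) * n_reps)
  k <- 0L
  for (np in n_train) {
    for (rep_i in seq_len(n_reps)) {
      draw <- with_seed(seed + rep_i, {
        # same replicate seed across n_train: VS is redrawn identically,
        # TS grows by resampling from the remainder
        if (scheme == "egsd") {
          vs <- sample(avail, vs_size)
          ts <- sample(setdiff(avail, vs), np)
        } else if (scheme == "wp") {
          vs <- sample(fam, vs_size)
          ts <- sample(setdiff(fam, vs), np)
        } else {
          vs <- sample(fam, vs_size)
          ts <- sample(pool, np)
        }
        list(vs = vs, ts = ts)
      })
      stopifnot(length(intersect(draw$vs, draw$ts)) == 0L)
      gebv <- gblup_predict(yv[draw$ts], K, draw$vs)
      k <- k + 1L
      out[[k]] <- tibble(
        scheme = scheme, trait = trait_name,
        population = population %||% NA_character_,
        marker_set = marker_set, n_train = np, rep = rep_i,
        r = predictive_ability(gebv$gebv, yv[draw$vs])
      )
      pred_sum[draw$vs] <- pred_sum[draw$vs] + gebv$gebv
      pred_n[draw$vs] <- pred_n[draw$vs] + 1L
    }
  }
  res <- list_rbind(out)
  seen <- pred_n > 0
  attr(res, "per_line") <- tibble(
    line = avail[seen],
    population = li$population[match(avail[seen], li$line)],
    mean_gebv = pred_sum[seen] / pred_n[seen],
    n_reps = pred_n[seen]
  )
  class(res) <- c("gs_cv", class(res))
  res
}

#' Summarise replicated cross-validation results
#'
#' @param cv A `gs_cv` tibble (or several row-bound together).
#' @return A tibble with mean and SD of the replicate predictive abilities
#'   per scheme/trait/population/marker set/training size.
#' @export
cv_summary <- function(cv) {
  cv |>
    as_tibble() |>
    group_by(.data$scheme, .data$trait, .data$population,
             .data$marker_set, .data$n_train) |>
    summarise(mean_r = mean(.data$r), sd_r = sd(.data$r),
              n_reps = dplyr::n(), .groups = "drop")
}

#' Mean predicted GEBV per line accumulated during cross-validation
#'
#' @param cv A `gs_cv` result from [run_gs_cv()].
#' @return Tibble `line`, `population`, `mean_gebv`, `n_reps`.
#' @export
cv_per_line <- function(cv) {
  pl <- attr(cv, "per_line")
  if (is.null(pl)) abort("no per-line predictions attached to this object")
  pl
}
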