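# build a factor for a model term like "line" or "line:env" from columns of
# the phenotype table
term_factor <- function(pheno, term) {
  cols <- strsplit(term, ":", fixed = TRUE)[[1]]
  bad <- setdiff(cols, names(pheno))
  if (length(bad)) abort(sprintf("unknown factor column(s): %s", paste(bad, collapse = ", ")))
  f <- do.call(interaction, c(unname(pheno[cols]), list(drop = TRUE, sep = ":")))
  droplevels(f)
}

#' Fit an all-random-effects model by EM-REML on Henderson's equations
#'
#' Fits `y = 1*mu + sum_r Z_r u_r + e`, `u_r ~ N(0, I sigma2_r)`,
#' `e ~ N(0, I sigma2_e)` to plot-level records by EM iterations on
#' Henderson's mixed-model equations. The factor with the most levels whose
#' incidence crossproduct is diagonal (typically the genotype-by-environment
#' interaction) is absorbed, so each iteration factors only the small
#' retained system. The restricted log-likelihood is evaluated every
#' iteration and is non-decreasing under EM; convergence is declared when
#' the largest relative change across variance components falls below
#' `tol`.
#'
#' @param pheno Plot-level tibble with a `value` column and the factor
#'   columns referenced by `factors` (e.g. from [sim_trials()]).
#' @param factors Character vector of random terms; `:` builds
#'   interactions (e.g. `"line:env"` for G-by-E, `"env:set"` for
#'   set-within-environment). Must include `"line"`.
#' @param trait Optional trait name; if given, `pheno` is filtered to
#'   `trait == trait` first.
#' @param tol Relative convergence tolerance on variance components.
#' @param max_iter Maximum EM iterations.
#' @return A `ranef_fit`: `vc` (tibble `term`, `variance` incl.
#'   `"residual"`), `mu`, `effects` (named list of tibbles `level`,
#'   `effect`), `loglik` (per-iteration restricted log-likelihood trace),
#'   `converged`, `n_iter`, `n`.
#' @export
fit_ranef_model <- function(pheno,
                            factors = c("line", "env", "line:env", "env:set"),
                            trait = NULL, tol = 1e-6, max_iter = 500L) {
  if (!is.null(trait)) pheno <- filter(pheno, .data$trait == !!trait)
  if (!"line" %in% factors) abort("`factors` must include \"line\"")
  if (!nrow(pheno)) abort("no phenotype records to fit")
  y <- pheno$value
  if (anyNA(y)) {
    keep <- !is.na(y)
    pheno <- pheno[keep, ]
    y <- y[keep]
  }
  n <- length(y)
  fs <- lapply(factors, function(tm) term_factor(pheno, tm))
  names(fs) <- factors
  q_r <- vapply(fs, nlevels, integer(1))
  if (any(q_r < 2)) {
    abort(sprintf("factor(s) with < 2 observed levels: %s",
                  paste(factors[q_r < 2], collapse = ", ")))
  }
  zs <- lapply(fs, function(f) {
    Matrix::sparseMatrix(i = seq_len(n), j = as.integer(f),
                         x = 1, dims = c(n, nlevels(f)))
  })
  w <- do.call(cbind, c(list(Matrix::Matrix(1, n, 1, sparse = TRUE)), zs))
  wtw <- Matrix::crossprod(w)
  wty <- as.numeric(Matrix::crossprod(w, y))
  yty <- sum(y^2)
  blk <- split(seq_len(1L + sum(q_r)) [-1L],
               rep(seq_along(q_r), q_r))  # MME columns per factor

  # absorb the largest factor whose Z'Z is diagonal
  diag_ok <- vapply(seq_along(zs), function(r) {
    ztz <- wtw[blk[[r]], blk[[r]]]
    Matrix::nnzero(ztz) == length(blk[[r]])
  }, logical(1))
  absorb <- if (any(diag_ok)) which(diag_ok)[which.max(q_r[diag_ok])] else 0L
  a_cols <- if (absorb > 0L) blk[[absorb]] else integer(0)
  k_cols <- setdiff(seq_len(1L + sum(q_r)), a_cols)
  m_kk <- as.matrix(wtw[k_cols, k_cols])
  m_ka <- wtw[k_cols, a_cols, drop = FALSE]
  d_a0 <- if (absorb > 0L) Matrix::diag(wtw[a_cols, a_cols]) else numeric(0)
  kept_of <- lapply(blk, function(b) match(intersect(b, k_cols), k_cols))

  vary <- var(y)
  n_cols <- 1L + sum(q_r)
  if (vary == 0) {
    # degenerate: constant response; all components zero, BLUPs flat
    effects <- lapply(fs, function(f) tibble(level = levels(f), effect = 0))
    return(structure(
      list(vc = tibble(term = c(factors, "residual"), variance = 0),
           mu = y[1], effects = effects, loglik = numeric(0),
           converged = TRUE, n_iter = 0L, n = n),
      class = "ranef_fit"
    ))
  }

  # solve the MME and evaluate the restricted log-likelihood at a given set
  # of components; returns solution, diag(C^-1), and ll
  eval_state <- function(s2, s2e) {
    lam <- s2e / s2
    pen_k <- numeric(length(k_cols))
    for (r in seq_along(factors)) pen_k[kept_of[[r]]] <- lam[r]
    if (absorb > 0L) {
      d <- d_a0 + lam[absorb]
      bd <- m_ka %*% Matrix::Diagonal(x = 1 / d)
      s_mat <- m_kk + diag(pen_k, length(k_cols)) -
        as.matrix(bd %*% Matrix::t(m_ka))
      rhs_k <- wty[k_cols] - as.numeric(bd %*% wty[a_cols])
    } else {
      s_mat <- m_kk + diag(pen_k, length(k_cols))
      rhs_k <- wty[k_cols]
    }
    ch <- chol((s_mat + t(s_mat)) / 2)
    x_k <- backsolve(ch, backsolve(ch, rhs_k, transpose = TRUE))
    s_inv <- chol2inv(ch)
    sol <- numeric(n_cols)
    sol[k_cols] <- x_k
    diag_cinv <- numeric(n_cols)
    diag_cinv[k_cols] <- diag(s_inv)
    logdet_c <- 2 * sum(log(diag(ch)))
    if (absorb > 0L) {
      sol[a_cols] <- (wty[a_cols] - as.numeric(Matrix::crossprod(m_ka, x_k))) / d
      bd <- as.matrix(bd)
      diag_cinv[a_cols] <- 1 / d + colSums(bd * (s_inv %*% bd))
      logdet_c <- logdet_c + sum(log(d))
    }
    ll <- -0.5 * (n * log(s2e) + sum(q_r * log(s2 / s2e)) + logdet_c -
                    log(s2e) + (yty - sum(sol * wty)) / s2e +
                    (n - 1) * log(2 * pi))
    list(sol = sol, diag_cinv = diag_cinv, ll = ll)
  }
  em_step <- function(st, s2, s2e) {
    s2e_new <- (yty - sum(st$sol * wty)) / (n - 1)
    s2_new <- s2
    for (r in seq_along(factors)) {
      u_r <- st$sol[blk[[r]]]
      s2_new[r] <- (sum(u_r^2) + s2e * sum(st$diag_cinv[blk[[r]]])) / q_r[r]
    }
    list(s2 = s2_new, s2e = s2e_new)
  }

  s2 <- setNames(rep(vary / (2 * length(factors)), length(factors)), factors)
  s2e <- vary / 2
  ll_trace <- numeric(0)
  converged <- FALSE
  prev_step <- NULL
  floor_v <- 1e-10 * vary

  for (iter in seq_len(max_iter)) {
    st <- eval_state(s2, s2e)
    ll_trace <- c(ll_trace, st$ll)
    up <- em_step(st, s2, s2e)
    theta_old <- c(s2, s2e)
    theta_new <- c(up$s2, up$s2e)
    step <- theta_new - theta_old
    # EM converges linearly, slowly so for small components; every few
    # iterations attempt an Aitken extrapolation along the step direction,
    # accepted only if the restricted likelihood does not decrease (keeps
    # the monotone-likelihood property of plain EM)
    if (iter %% 3L == 0L && !is.null(prev_step)) {
      rate <- ifelse(abs(prev_step) > 0, step / prev_step, 0)
      rate <- pmin(pmax(rate, 0), 0.995)
      theta_acc <- pmax(theta_new + step * rate / (1 - rate), floor_v)
      st_acc <- eval_state(theta_acc[seq_along(s2)],
                           theta_acc[length(theta_acc)])
      if (is.finite(st_acc$ll) && st_acc$ll >= st$ll) {
        theta_new <- theta_acc
        step <- theta_new - theta_old
      }
    }
    prev_step <- step
    # components below 0.1% of total variance are judged on absolute
    # change: EM approaches a zero component sublinearly and a purely
    # relative criterion would never trigger there
    rel <- max(abs(theta_new - theta_old) /
                 pmax(abs(theta_old), 1e-3 * vary))
    s2 <- pmax(theta_new[seq_along(s2)], floor_v)
    # keep the residual strictly positive: the MME degenerate at s2e = 0
    s2e <- max(unname(theta_new[length(theta_new)]), floor_v)
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  st <- eval_state(s2, s2e)
  sol <- st$sol
  if (!converged) {
    warn(sprintf("EM-REML did not reach tol = %g in %d iterations (last rel change %.2g)",
                 tol, max_iter, rel))
  }
  effects <- lapply(seq_along(factors), function(r) {
    tibble(level = levels(fs[[r]]), effect = sol[blk[[r]]])
  })
  names(effects) <- factors
  structure(
    list(vc = tibble(term = c(factors, "residual"),
                     variance = c(unname(s2), s2e)),
         mu = sol[1], effects = effects, loglik = ll_trace,
         converged = converged, n_iter = length(ll_trace), n = n),
    class = "ranef_fit"
  )
}

#' @export
print.ranef_fit <- function(x, ...) {
  cat(sprintf("<ranef_fit> %d records, %d EM iterations%s\n", x$n, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  print(x$vc)
  invisible(x)
}

#' Extract per-genotype BLUPs from a fitted random model
#'
#' `BLUP_i = mu_hat + u_hat_line,i`. Only genotypes observed in the data
#' appear (absent genotypes are not zero-filled). BLUPs are shrunken:
#' their variance never exceeds that of the raw genotype means.
#'
#' @param fit A [fit_ranef_model()] object.
#' @param include_mean Add the grand mean so values read in trait units.
#' @return A tibble `line`, `blup`.
#' @export
genotype_blups <- function(fit, include_mean = TRUE) {
  if (!"line" %in% names(fit$effects)) abort("fit contains no genotype factor")
  eff <- fit$effects[["line"]]
  tibble(line = eff$level,
         blup = (if (include_mean) fit$mu else 0) + eff$effect)
}

#' One BLUP per line per trait from plot-level records
#'
#' Fits the all-random model once per trait and returns the stacked BLUP
#' table used as the "observed" side of every predictive-ability
#' correlation. By default the yield-type model adds the days-to-maturity
#' class as an extra random factor when a `dtm_class` column is present and
#' the trait is listed in `dtm_traits`.
#'
#' @param pheno Long plot-level tibble (`line`, `env`, `set`, `block`,
#'   `dtm_class`, `trait`, `value`).
#' @param factors Base random terms.
#' @param dtm_traits Traits whose model also includes `dtm_class`.
#' @param ... Passed to [fit_ranef_model()].
#' @return A tibble `line`, `trait`, `blup`.
#' @export
gs_blups <- function(pheno, factors = c("line", "env", "line:env", "env:set"),
                     dtm_traits = "yield", ...) {
  traits <- unique(pheno$trait)
  purrr::map(traits, function(tr) {
    fac <- factors
    if (tr %in% dtm_traits && "dtm_class" %in% names(pheno)) {
      fac <- c(fac, "dtm_class")
    }
    fit <- fit_ranef_model(pheno, factors = fac, trait = tr, ...)
    mutate(genotype_blups(fit), trait = tr, .after = "line")
  }) |> list_rbind()
}
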