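# balanced one-way phenotype table: n_g genotypes x r reps
one_way_pheno <- function(n_g, r, sg = 2, se = 1, mu = 10, seed = 1) {
  set.seed(seed)
  g <- rnorm(n_g, 0, sg)
  tibble::tibble(
    line = rep(sprintf("G%03d", 1:n_g), each = r),
    env = "env01", set = "set1", block = rep(1:r, n_g),
    dtm_class = "dtm1", trait = "t",
    value = mu + rep(g, each = r) + rnorm(n_g * r, 0, se)
  )
}

test_that("balanced one-way EM-REML equals the closed-form ANOVA estimators", {
  ph <- one_way_pheno(40, 5, seed = 2)
  fit <- fit_ranef_model(ph, factors = "line")
  # ANOVA oracle: sigma_g = (MSB - MSW) / r, sigma_e = MSW
  a <- anova(lm(value ~ line, data = ph))
  msb <- a[["Mean Sq"]][1]
  msw <- a[["Mean Sq"]][2]
  expect_equal(fit$vc$variance[fit$vc$term == "residual"], msw,
               tolerance = 1e-4)
  expect_equal(fit$vc$variance[fit$vc$term == "line"], (msb - msw) / 5,
               tolerance = 1e-3)
  # restricted likelihood non-decreasing at every EM iteration
  expect_true(all(diff(fit$loglik) > -1e-8 * abs(fit$loglik[1])))
  # balanced design: genotype deviations sum to ~0
  expect_lt(abs(sum(fit$effects$line$effect)), 1e-6 * sd(ph$value) * 40)
})

test_that("noiseless data drive the residual to zero and BLUPs to genotype means", {
  ph <- one_way_pheno(15, 3, se = 0, seed = 3)
  ph$value <- round(ph$value, 10)
  fit <- suppressWarnings(fit_ranef_model(ph, factors = "line"))
  expect_lt(fit$vc$variance[fit$vc$term == "residual"],
            1e-4 * fit$vc$variance[1])
  bl <- genotype_blups(fit)
  means <- tapply(ph$value, ph$line, mean)
  expect_equal(bl$blup, as.numeric(means[bl$line]), tolerance = 1e-3)
})

test_that("BLUPs shrink: bounded variance, constant data, direction", {
  ph <- one_way_pheno(30, 4, sg = 1, se = 2, seed = 4)
  fit <- fit_ranef_model(ph, factors = "line")
  bl <- genotype_blups(fit)
  means <- tapply(ph$value, ph$line, mean)
  expect_lt(var(bl$blup), var(as.numeric(means)))

  # all plots identical -> every BLUP equals that value
  ph0 <- one_way_pheno(8, 3, sg = 0, se = 0)
  ph0$value <- 7
  fit0 <- suppressWarnings(fit_ranef_model(ph0, factors = "line"))
  expect_equal(genotype_blups(fit0)$blup, rep(7, 8), tolerance = 1e-6)

  # the less-replicated (noisier-mean) genotype is shrunk harder: equal raw
  # deviations, 10 vs 2 plots
  ph2 <- tibble::tibble(
    line = c(rep("A", 10), rep("B", 2), rep(sprintf("C%d", 1:6), each = 6)),
    env = "e", set = "s", block = 1, dtm_class = "d", trait = "t",
    value = c(rnorm(10, 14, 1), rnorm(2, 14, 1), rnorm(36, 10, 1))
  )
  ph2$value[1:10] <- 14 + scale(ph2$value[1:10])[, 1]
  ph2$value[11:12] <- 14 + scale(ph2$value[11:12])[, 1]  # both means = 14
  fit2 <- fit_ranef_model(ph2, factors = "line")
  bl2 <- genotype_blups(fit2, include_mean = FALSE)
  dev <- setNames(bl2$blup, bl2$line)
  expect_gt(dev[["A"]], dev[["B"]])  # same raw mean, more data, less shrink
  expect_gt(dev[["B"]], 0)
})

test_that("multi-factor fit matches Henderson's equations and lme4", {
  skip_if_not_installed("lme4")
  set.seed(6)
  n_g <- 40; n_e <- 4; n_b <- 2
  g <- rnorm(n_g, 0, 2); e <- rnorm(n_e, 0, 1.5)
  ge <- matrix(rnorm(n_g * n_e, 0, 1), n_g)
  ph <- tidyr::expand_grid(i = 1:n_g, j = 1:n_e, block = 1:n_b)
  ph <- dplyr::mutate(ph,
    line = sprintf("G%02d", i), env = sprintf("E%d", j),
    set = "s", dtm_class = "d", trait = "t",
    value = 5 + g[i] + e[j] + ge[cbind(i, j)] + rnorm(dplyr::n(), 0, 1)
  )
  fit <- fit_ranef_model(ph, factors = c("line", "env", "line:env"))

  # dense Henderson MME oracle at the fitted components
  vc <- setNames(fit$vc$variance, fit$vc$term)
  X <- matrix(1, nrow(ph))
  Zg <- model.matrix(~ 0 + line, ph)
  Ze <- model.matrix(~ 0 + env, ph)
  Zge <- model.matrix(~ 0 + interaction(line, env), ph)
  W <- cbind(X, Zg, Ze, Zge)
  lam <- vc["residual"] / c(vc["line"], vc["env"], vc["line:env"])
  D <- diag(c(0, rep(lam, c(n_g, n_e, n_g * n_e))))
  sol <- solve(crossprod(W) + D, crossprod(W, ph$value))
  expect_equal(fit$mu, sol[1], tolerance = 1e-8)
  expect_equal(fit$effects$line$effect, unname(sol[2:(n_g + 1)]),
               tolerance = 1e-8)

  # independent REML oracle: lme4 on the same model
  lf <- lme4::lmer(value ~ (1 | line) + (1 | env) + (1 | line:env),
                   data = ph, REML = TRUE)
  vc_l <- as.data.frame(lme4::VarCorr(lf))
  get <- function(t) vc_l$vcov[vc_l$grp == t]
  expect_equal(vc[["line"]], get("line"), tolerance = 1e-3)
  expect_equal(vc[["line:env"]], get("line:env"), tolerance = 5e-3)
  expect_equal(vc[["residual"]], get("Residual"), tolerance = 1e-3)
  expect_equal(fit$loglik[fit$n_iter], as.numeric(stats::logLik(lf)),
               tolerance = 1e-4)
})

test_that("variance components are recovered from simulated records", {
  # truth: s2_g = 4, s2_E = 2, s2_gE = 1, s2_e = 1; 100 x 4 x 2
  est <- sapply(1:12, function(s) {
    set.seed(1000 + s)
    n_g <- 100; n_e <- 4
    g <- rnorm(n_g, 0, 2); e <- rnorm(n_e, 0, sqrt(2))
    ge <- matrix(rnorm(n_g * n_e), n_g)
    ph <- tidyr::expand_grid(i = 1:n_g, j = 1:n_e, block = 1:2)
    ph <- dplyr::mutate(ph,
      line = sprintf("G%03d", i), env = sprintf("E%d", j),
      set = "s", dtm_class = "d", trait = "t",
      value = g[i] + e[j] + ge[cbind(i, j)] + rnorm(dplyr::n())
    )
    fit <- suppressWarnings(
      fit_ranef_model(ph, factors = c("line", "env", "line:env"))
    )
    setNames(fit$vc$variance, fit$vc$term)
  })
  m <- rowMeans(est)
  expect_equal(m[["line"]], 4, tolerance = 0.15 * 4)
  expect_equal(m[["line:env"]], 1, tolerance = 0.15)
  expect_equal(m[["residual"]], 1, tolerance = 0.15)
})

test_that("BLUP distribution is smooth for noise-dominated simulations", {
  set.seed(9)
  ph <- one_way_pheno(120, 3, sg = 0.5, se = 3, seed = 10)
  fit <- fit_ranef_model(ph, factors = "line")
  bl <- genotype_blups(fit)
  expect_gt(stats::shapiro.test(bl$blup)$p.value, 0.01)
})

test_that("gs_blups stacks traits and validates factors", {
  sim <- sim_gs_dataset(family_size = 15, n_mixed = 0, n_founders = 10,
                        map = tiny_map(2, 20), seed = 3)
  bl <- suppressWarnings(gs_blups(sim$pheno))
  expect_setequal(unique(bl$trait), c("protein", "oil", "yield"))
  expect_equal(sum(bl$trait == "yield"), 60)
  expect_error(fit_ranef_model(sim$pheno, trait = "yield",
                               factors = c("line", "nope")), "unknown factor")
  expect_error(fit_ranef_model(sim$pheno[0, ], factors = "line"), "no phenotype")
})
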