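# shared panel with a heritable and a null trait
cv_fixture <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      map <- tiny_map(4, 40)
      sim <- sim_gs_dataset(
        n_families = 2, family_size = 90, n_mixed = 60, n_founders = 16,
        map = map,
        traits = list(hi = list(h2 = 0.8, n_qtl = 30, pop_offsets = c(), mu = 0)),
        seed = 17
      )
      g <- marker_qc(sim$geno)
      li <- line_info(g)
      hi <- dplyr::left_join(
        tibble::tibble(line = li$line),
        dplyr::filter(sim$truth, trait == "hi"), by = "line"
      )
      K <- additive_kinship(g)
      va <- var(hi$g) / mean(diag(kinship_matrix(K)))
      set.seed(99)
      blups <- dplyr::bind_rows(
        tibble::tibble(line = hi$line, trait = "hi",
                       blup = hi$g + rnorm(nrow(hi), 0, sqrt(va / 4))),
        tibble::tibble(line = hi$line, trait = "null",
                       blup = rnorm(nrow(hi)))
      )
      val <<- list(g = g, K = K, blups = blups)
    }
    val
  }
})

test_that("predictive ability and prediction accuracy follow their definitions", {
  expect_equal(predictive_ability(1:4, 1:4), 1)
  expect_equal(predictive_ability(1:4, -(1:4)), -1)
  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 9)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(predictive_ability(x, y), r_hand)
  expect_error(predictive_ability(c(1, 1, 1), 1:3), "zero variance")
  expect_error(predictive_ability(1:2, 1:2), "at least 3")

  expect_equal(round(prediction_accuracy(0.81, 0.82), 2), 0.89)
  expect_equal(round(prediction_accuracy(0.71, 0.78), 2), 0.80)
  expect_equal(round(prediction_accuracy(0.26, 0.17), 2), 0.63)
  expect_equal(prediction_accuracy(0.4, 1), 0.4)
  expect_error(prediction_accuracy(0.4, 0), "\\(0, 1\\]")
})

test_that("whole-dataset cross-validation: signal, null, determinism", {
  fx <- cv_fixture()
  cv_hi <- run_gs_cv(fx$g, fx$blups, "egsd", trait = "hi", n_train = 100,
                     n_reps = 20, K = fx$K, seed = 5)
  expect_gt(mean(cv_hi$r), 0.6)
  expect_true(all(cv_hi$r >= -1 & cv_hi$r <= 1))

  # null trait: replicates sharing one fixed phenotype vector are
  # correlated, so the unconditional mean is taken over independent null
  # draws; it must sit within 3 SE of zero
  set.seed(41)
  null_r <- unlist(lapply(1:10, function(i) {
    bl_i <- tibble::tibble(line = line_info(fx$g)$line, trait = "null",
                           blup = rnorm(nrow(fx$g)))
    run_gs_cv(fx$g, bl_i, "egsd", trait = "null", n_train = 100,
              n_reps = 5, K = fx$K, seed = 600 + i)$r
  }))
  expect_lt(abs(mean(null_r)), 3 * sd(null_r) / sqrt(10))

  # same seed -> identical replicate sequence; different seed differs
  cv_rep <- run_gs_cv(fx$g, fx$blups, "egsd", trait = "hi", n_train = 100,
                      n_reps = 20, K = fx$K, seed = 5)
  expect_identical(cv_hi$r, cv_rep$r)
  cv_other <- run_gs_cv(fx$g, fx$blups, "egsd", trait = "hi", n_train = 100,
                        n_reps = 20, K = fx$K, seed = 7)
  expect_false(identical(cv_hi$r, cv_other$r))

  expect_error(run_gs_cv(fx$g, fx$blups, "egsd", trait = "hi",
                         n_train = 1000, n_reps = 2), "needs >=")
})

test_that("noiseless marker-determined phenotype is predicted almost perfectly", {
  fx <- cv_fixture()
  # phenotype = exact linear function of the markers
  set.seed(12)
  g_exact <- tibble::tibble(
    line = line_info(fx$g)$line, trait = "exact",
    blup = as.numeric(impute_marker_means(fx$g) %*%
                        rnorm(ncol(fx$g), 0, 0.2))
  )
  cv <- run_gs_cv(fx$g, g_exact, "egsd", trait = "exact", n_train = 180,
                  n_reps = 10, K = fx$K, seed = 8)
  expect_gt(mean(cv$r), 0.95)
})

test_that("within-population cross-validation stays inside the family", {
  fx <- cv_fixture()
  cv <- run_gs_cv(fx$g, fx$blups, "wp", trait = "hi", population = "Pop1",
                  n_train = 50, n_reps = 20, K = fx$K, seed = 9)
  expect_gt(mean(cv$r), 0.3)
  pl <- cv_per_line(cv)
  expect_true(all(pl$population == "Pop1"))

  # null trait: mean stays small (replicates share one phenotype vector,
  # so a modest panel-conditional offset is expected)
  cv_null <- run_gs_cv(fx$g, fx$blups, "null", scheme = "wp",
                       population = "Pop1", n_train = 50, n_reps = 20,
                       K = fx$K, seed = 10)
  expect_lt(abs(mean(cv_null$r)), 0.3)

  expect_error(run_gs_cv(fx$g, fx$blups, "wp", trait = "hi",
                         population = "Pop2", n_train = 80, n_reps = 2,
                         K = fx$K), "Pop2")
  expect_error(run_gs_cv(fx$g, fx$blups, "wp", trait = "hi", n_train = 50),
               "population")
})

test_that("across-population cross-validation excludes full sibs from the pool", {
  map <- tiny_map(3, 30)
  # one mixed pedigree reuses Pop1's parents -> its lines are full sibs
  sim <- sim_gs_dataset(
    n_families = 2, family_size = 40, n_mixed = 40, n_mixed_pedigrees = 4,
    n_fullsib_mixed = 1, n_founders = 12, map = map,
    traits = list(hi = list(h2 = 0.8, n_qtl = 20, pop_offsets = c(), mu = 0)),
    seed = 23
  )
  g <- marker_qc(sim$geno)
  li <- line_info(g)
  set.seed(1)
  bl <- tibble::tibble(line = li$line, trait = "hi", blup = rnorm(nrow(li)))
  # pool for Pop1 = 120 lines minus Pop1 (40) minus the full-sib Ped1
  # (10) = 70; n_train = 71 must fail, 70 must work
  expect_error(
    run_gs_cv(g, bl, "ap", trait = "hi", population = "Pop1", n_train = 71,
              n_reps = 2, seed = 2),
    "full-sibs"
  )
  cv <- run_gs_cv(g, bl, "ap", trait = "hi", population = "Pop1",
                  n_train = 70, n_reps = 3, seed = 2)
  expect_equal(nrow(cv), 3)
  # for Pop2 (no full-sib pedigree) the pool is larger: 80 lines
  cv2 <- run_gs_cv(g, bl, "ap", trait = "hi", population = "Pop2",
                   n_train = 80, n_reps = 2, seed = 2)
  expect_equal(nrow(cv2), 2)
  expect_error(
    run_gs_cv(g, bl, "ap", trait = "hi", population = "Pop2", n_train = 81,
              n_reps = 2, seed = 2),
    "max feasible"
  )
})

test_that("cv_summary averages replicates and keeps the grouping", {
  fx <- cv_fixture()
  cv <- run_gs_cv(fx$g, fx$blups, "egsd", trait = "hi",
                  n_train = c(60, 120), n_reps = 5, K = fx$K, seed = 11)
  s <- cv_summary(cv)
  expect_equal(nrow(s), 2)
  expect_equal(s$n_reps, c(5, 5))
  manual <- mean(cv$r[cv$n_train == 60])
  expect_equal(s$mean_r[s$n_train == 60], manual)
})
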