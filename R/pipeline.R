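# weak but stable content hash for cache invalidation
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 2166136261
  step <- max(1L, length(raw) %/% 4096L)
  for (i in seq(1L, length(raw), by = step)) {
    h <- (h * 16777619 + as.integer(raw[i])) %% 2^31
  }
  sprintf("%08x-%d", as.integer(h), length(raw))
}

#' Configuration for the end-to-end genomic-selection pipeline
#'
#' Collects simulation settings and analysis grids. All stages derive
#' their seeds from `seed`; rerunning with the same config and seed gives
#' identical results.
#'
#' @param seed Master seed.
#' @param sim Named list of arguments for [sim_gs_dataset()] (less `seed`).
#' @param traits Traits to analyse (`NULL` = all simulated).
#' @param schemes Cross-validation designs to run.
#' @param n_train_egsd,n_train_ap Training-set size sweeps.
#' @param n_train_wp Within-population training-set size.
#' @param vs_egsd,vs_family Validation-set sizes (whole-panel; family).
#' @param n_reps Cross-validation replicates per configuration.
#' @param marker_sets Density sets evaluated at the maximum training size
#'   (any of `"all"`, `"tag"`, `"half_tag"`, `"4th_tag"`, `"8th_tag"`).
#' @param r2_threshold LD threshold for tag-SNP selection.
#' @param inflation_trait Trait used for the structure-inflation
#'   decomposition (the divergent-population trait by default).
#' @param alpha Significance level for the LSD report.
#' @return A `gs_config` list.
#' @export
gs_config <- function(seed = 1L, sim = list(), traits = NULL,
                      schemes = c("egsd", "wp", "ap"),
                      n_train_egsd = seq(50, 400, by = 50),
                      n_train_wp = 50,
                      n_train_ap = seq(50, 300, by = 50),
                      vs_egsd = 50, vs_family = 20, n_reps = 100,
                      marker_sets = c("all", "tag", "half_tag", "4th_tag", "8th_tag"),
                      r2_threshold = 0.8, inflation_trait = "oil",
                      alpha = 0.05) {
  structure(
    list(seed = seed, sim = sim, traits = traits, schemes = schemes,
         n_train_egsd = n_train_egsd, n_train_wp = n_train_wp,
         n_train_ap = n_train_ap, vs_egsd = vs_egsd, vs_family = vs_family,
         n_reps = n_reps, marker_sets = marker_sets,
         r2_threshold = r2_threshold, inflation_trait = inflation_trait,
         alpha = alpha),
    class = "gs_config"
  )
}

# run fun() or reuse the cached result if config hash matches
pipeline_stage <- function(name, hash, fun, out_dir, quiet) {
  if (!is.null(out_dir)) {
    cache <- file.path(out_dir, paste0(name, ".rds"))
    tag <- file.path(out_dir, paste0(name, ".hash"))
    if (file.exists(cache) && file.exists(tag) &&
        identical(readLines(tag, warn = FALSE)[1], hash)) {
      if (!quiet) message("[", name, "] cached")
      return(readRDS(cache))
    }
  }
  if (!quiet) message("[", name, "] running")
  res <- tryCatch(fun(), error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
  if (!is.null(out_dir)) {
    saveRDS(res, cache)
    writeLines(hash, tag)
  }
  res
}

#' Run the full genomic-selection analysis pipeline
#'
#' simulate -> marker QC -> tag-SNP sets -> phenotypic BLUPs -> genomic
#' heritability -> the three cross-validation designs over training-size
#' and marker-density grids -> genotype PCA -> structure-inflation
#' decomposition -> ANOVA/LSD report. Deterministic given the config seed;
#' with `out_dir` set, stage results are cached and reruns resume from any
#' stage whose inputs are unchanged (config-hash invalidation).
#'
#' @param config A [gs_config()].
#' @param out_dir Optional directory for cached stage results and summary
#'   CSVs.
#' @param quiet Suppress stage progress messages.
#' @return A list: `sim`, `geno` (QC-filtered), `marker_sets`, `blups`,
#'   `h2`, `cv` (all replicate rows), `cv_summary`, `pca`, `inflation`,
#'   `lsd`, `config`.
#' @export
run_gs_pipeline <- function(config = gs_config(), out_dir = NULL,
                            quiet = FALSE) {
  stopifnot(inherits(config, "gs_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  seed <- config$seed

  sim <- pipeline_stage("simulate", config_hash(list(config$sim, seed)),
                        function() {
                          do.call(sim_gs_dataset, c(config$sim, list(seed = seed)))
                        }, out_dir, quiet)
  h_sim <- config_hash(list(config$sim, seed))

  geno <- pipeline_stage("qc", config_hash(list(h_sim, "qc")), function() {
    marker_qc(sim$geno)
  }, out_dir, quiet)

  msets <- pipeline_stage(
    "tags", config_hash(list(h_sim, config$r2_threshold)),
    function() marker_density_sets(geno, config$r2_threshold),
    out_dir, quiet
  )

  blups <- pipeline_stage("blups", config_hash(list(h_sim, "blups")),
                          function() gs_blups(sim$pheno), out_dir, quiet)

  K_all <- additive_kinship(geno)
  h2 <- pipeline_stage("h2", config_hash(list(h_sim, "h2")), function() {
    gs_heritability(blups, K = K_all)
  }, out_dir, quiet)

  traits <- config$traits %||% unique(blups$trait)
  pops <- grep("^Pop", unique(line_info(geno)$population), value = TRUE)
  h_cv <- config_hash(list(h_sim, config[c(
    "schemes", "n_train_egsd", "n_train_wp", "n_train_ap", "vs_egsd",
    "vs_family", "n_reps", "marker_sets", "traits"
  )]))
  cv <- pipeline_stage("cv", h_cv, function() {
    runs <- list()
    per_line <- list()
    for (tr in traits) {
      if ("egsd" %in% config$schemes) {
        runs[[length(runs) + 1L]] <- run_gs_cv(
          geno, blups, "egsd", trait = tr, n_train = config$n_train_egsd,
          vs_size = config$vs_egsd, n_reps = config$n_reps, K = K_all,
          seed = derive_seed(seed, "cv", "egsd", tr)
        )
        for (ms in setdiff(config$marker_sets, "all")) {
          g_ms <- select_markers(geno, msets[[ms]])
          res <- run_gs_cv(
            g_ms, blups, "egsd", trait = tr,
            n_train = max(config$n_train_egsd), vs_size = config$vs_egsd,
            n_reps = config$n_reps, marker_set = ms,
            seed = derive_seed(seed, "cv", "egsd", tr, ms)
          )
          runs[[length(runs) + 1L]] <- res
          if (tr == config$inflation_trait) {
            per_line[[ms]] <- cv_per_line(res)
          }
        }
        if (tr == config$inflation_trait) {
          # per-line means at the maximum training size, all markers
          res_all <- run_gs_cv(
            geno, blups, "egsd", trait = tr,
            n_train = max(config$n_train_egsd), vs_size = config$vs_egsd,
            n_reps = config$n_reps, K = K_all,
            seed = derive_seed(seed, "cv", "egsd", tr, "all-max")
          )
          per_line[["all"]] <- cv_per_line(res_all)
        }
      }
      for (pop in pops) {
        if ("wp" %in% config$schemes) {
          runs[[length(runs) + 1L]] <- run_gs_cv(
            geno, blups, "wp", trait = tr, population = pop,
            n_train = config$n_train_wp, vs_size = config$vs_family,
            n_reps = config$n_reps, K = K_all,
            seed = derive_seed(seed, "cv", "wp", tr, pop)
          )
        }
        if ("ap" %in% config$schemes) {
          runs[[length(runs) + 1L]] <- run_gs_cv(
            geno, blups, "ap", trait = tr, population = pop,
            n_train = config$n_train_ap, vs_size = config$vs_family,
            n_reps = config$n_reps, K = K_all,
            seed = derive_seed(seed, "cv", "ap", tr, pop)
          )
        }
      }
    }
    list(rows = list_rbind(lapply(runs, as_tibble)), per_line = per_line)
  }, out_dir, quiet)

  inflation <- pipeline_stage("inflation", config_hash(list(h_cv, "infl")),
    function() {
      tr_blups <- filter(blups, .data$trait == config$inflation_trait)
      purrr::imap(cv$per_line, function(pl, ms) {
        inflation_decomposition(pl, blups = tr_blups, marker_set = ms)
      })
    }, out_dir, quiet)

  pca <- pipeline_stage("pca", config_hash(list(h_sim, "pca")),
                        function() genotype_pca(geno), out_dir, quiet)

  cv_sum <- cv_summary(cv$rows)
  lsd <- pipeline_stage("lsd", config_hash(list(h_cv, config$alpha)),
    function() {
      out <- list()
      for (tr in traits) {
        sweep_rows <- filter(cv$rows, .data$scheme == "egsd",
                             .data$trait == tr, .data$marker_set == "all",
                             .data$n_train %in% config$n_train_egsd)
        if (length(unique(sweep_rows$n_train)) >= 2) {
          out[[paste0(tr, "_n_train")]] <-
            anova_fisher_lsd(sweep_rows, "n_train", alpha = config$alpha)
        }
        dens_rows <- filter(cv$rows, .data$scheme == "egsd",
                            .data$trait == tr,
                            .data$n_train == max(config$n_train_egsd))
        if (length(unique(dens_rows$marker_set)) >= 2) {
          out[[paste0(tr, "_marker_set")]] <-
            anova_fisher_lsd(dens_rows, "marker_set", alpha = config$alpha)
        }
      }
      out
    }, out_dir, quiet)

  if (!is.null(out_dir)) {
    utils::write.csv(cv_sum, file.path(out_dir, "cv_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(h2, file.path(out_dir, "heritability.csv"),
                     row.names = FALSE)
    write_blup_csv(blups, file.path(out_dir, "blups.csv"))
  }
  list(sim = sim, geno = geno, marker_sets = msets, blups = blups, h2 = h2,
       cv = cv$rows, cv_per_line = cv$per_line, cv_summary = cv_sum,
       pca = pca, inflation = inflation, lsd = lsd, config = config)
}
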