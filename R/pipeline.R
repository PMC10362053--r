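#' Run the full analysis pipeline
#'
#' Chains the package's stages in dependency order: obtain trial data
#' (either read from the paths in `config$io` or generated by the synthetic
#' module), compute the crop-model potential yield where trials carry
#' phenology dates and weather is available, clean the trials and fit the
#' per-cultivar coefficients, run the plasticity scenarios and genetic-gain
#' regressions, and (when genotypes/pedigree are available or synthesized)
#' the relationship matrices, heritability and cross-validated BLUP. Every
#' output table is written to `config$io$out_dir` and recorded in a JSON
#' manifest together with the resolved configuration and seed.
#'
#' @param config a configuration list from [default_config()] or
#'   [read_config()].
#' @param stages character vector choosing stages:
#'   any of `"coefficients"`, `"scenarios"`, `"gain"`, `"quantgen"`.
#' @return Invisibly, the manifest list (`outputs`, `seed`, `config`,
#'   `row_counts`).
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("coefficients", "scenarios", "gain",
                                    "quantgen")) {
  out_dir <- config$io$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  manifest <- list(seed = seed, config = config, outputs = list(),
                   row_counts = list())
  note <- function(name, path, n) {
    manifest$outputs[[name]] <<- path
    manifest$row_counts[[name]] <<- n
  }
  params <- do.call(cgm_params, config$cgm)
  cfg_spy <- spy_config(config$spy$spy, config$spy$min_trials,
                        config$spy$outlier_sd)
  # --- inputs ---------------------------------------------------------------
  synthetic <- is.null(config$io$trials)
  truth <- NULL
  if (synthetic) {
    truth <- gen_truth(config$synth$n_cultivars, seed = seed,
                       beta_gain = 0.0102)
    trials <- gen_trials(truth, env_count = config$synth$env_count,
                         seed = seed + 1, sd_resid = config$synth$sd_resid,
                         spy = cfg_spy$spy)
  } else {
    trials <- read_trials_csv(config$io$trials)
  }
  if (!"yp_t_ha" %in% names(trials) ||
      any(!is.finite(trials$yp_t_ha))) {
    if (!is.null(config$io$weather)) {
      weather <- read_weather_csv(config$io$weather)
      trials <- add_potential_yield(trials, weather, params)
    } else if (!"yp_t_ha" %in% names(trials))
      stop("trials carry no yp_t_ha column and no weather file is configured")
  }
  write_trials_csv(trials, file.path(out_dir, "trials_yp.csv"))
  note("trials", file.path(out_dir, "trials_yp.csv"), nrow(trials))
  # --- coefficients ---------------------------------------------------------
  coeffs <- NULL
  if ("coefficients" %in% stages || "scenarios" %in% stages ||
      "gain" %in% stages || "quantgen" %in% stages) {
    coeffs <- fit_all_cultivars(trials, cfg_spy)
    if (!is.null(truth))
      coeffs$release_year <-
        truth$release_year[match(coeffs$cultivar_id, truth$cultivar_id)]
    write_coefficients_csv(coeffs, file.path(out_dir, "coefficients.csv"))
    note("coefficients", file.path(out_dir, "coefficients.csv"), nrow(coeffs))
  }
  # --- scenarios ------------------------------------------------------------
  if ("scenarios" %in% stages) {
    spec <- scenario_spec(config$scenarios$alphas, config$scenarios$beta_fixed,
                          cfg_spy$spy)
    sc <- run_scenarios(trials$yp_t_ha, trials$year, spec)
    utils::write.csv(sc$decades, file.path(out_dir, "scenarios.csv"),
                     row.names = FALSE)
    note("scenarios", file.path(out_dir, "scenarios.csv"), nrow(sc$decades))
  }
  # --- genetic gain ---------------------------------------------------------
  if ("gain" %in% stages && "release_year" %in% names(coeffs) &&
      sum(is.finite(coeffs$release_year)) >= 3) {
    gg <- subgroup_gain(coeffs)
    gain <- data.frame(coefficient = c("alpha", "beta"),
                       slope = c(gg$all$alpha$slope, gg$all$beta$slope),
                       slope_kg_ha_yr = c(gg$all$alpha$slope_per_1000,
                                          gg$all$beta$slope_per_1000),
                       p_value = c(gg$all$alpha$p_value, gg$all$beta$p_value),
                       n = c(gg$all$alpha$n, gg$all$beta$n))
    utils::write.csv(gain, file.path(out_dir, "genetic_gain.csv"),
                     row.names = FALSE)
    note("genetic_gain", file.path(out_dir, "genetic_gain.csv"), nrow(gain))
  }
  # --- quantitative genetics ------------------------------------------------
  if ("quantgen" %in% stages) {
    if (synthetic) {
      gp <- gen_genotypes_pedigree(
        n_founders = config$synth$n_founders,
        n_per_gen = config$synth$n_per_gen,
        generations = config$synth$generations,
        m_snps = config$synth$m_snps, n_causal = config$synth$n_causal,
        h2_alpha = config$synth$h2_alpha, h2_beta = config$synth$h2_beta,
        seed = seed + 2)
      gm <- gp$genotypes; ped <- gp$pedigree
      y <- as.matrix(gp$truth[, c("alpha", "beta")])
      rownames(y) <- gp$truth$id
    } else {
      gm <- if (grepl("\\.vcf(\\.gz)?$", config$io$genotypes))
        read_genotypes_vcf(config$io$genotypes)$genotypes
      else read_genotypes_tsv(config$io$genotypes)
      ped <- if (!is.null(config$io$pedigree))
        read_pedigree_csv(config$io$pedigree) else NULL
      common <- intersect(rownames(gm), coeffs$cultivar_id)
      gm <- gm[common, , drop = FALSE]
      y <- as.matrix(coeffs[match(common, coeffs$cultivar_id),
                            c("alpha", "beta")])
      rownames(y) <- common
    }
    gm <- filter_maf(gm, config$quantgen$maf_min)
    G <- genomic_relationship(gm)
    utils::write.csv(as.data.frame(unclass(G)),
                     file.path(out_dir, "grm.csv"))
    note("grm", file.path(out_dir, "grm.csv"), nrow(G))
    A <- if (!is.null(ped)) pedigree_relationship(ped) else NULL
    sampler <- gibbs_config(config$quantgen$n_iter, config$quantgen$burn_in,
                            seed = seed + 3)
    fit <- fit_multitrait_blup(y, model = config$quantgen$model, G = G, A = A,
                               sampler = sampler)
    h2 <- data.frame(trait = colnames(y),
                     h2 = vapply(seq_len(ncol(y)), function(tr)
                       heritability(fit, tr), numeric(1)))
    utils::write.csv(h2, file.path(out_dir, "heritability.csv"),
                     row.names = FALSE)
    note("heritability", file.path(out_dir, "heritability.csv"), nrow(h2))
    cv <- kfold_cv(y, model = config$quantgen$model, G = G, A = A,
                   k = config$quantgen$k, reps = config$quantgen$reps,
                   seed = seed + 4, sampler = sampler)
    utils::write.csv(cv$summary, file.path(out_dir, "cv_summary.csv"),
                     row.names = FALSE)
    note("cv", file.path(out_dir, "cv_summary.csv"), nrow(cv$summary))
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(manifest)
}
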