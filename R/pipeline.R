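#' Default end-to-end pipeline configuration
#'
#' Every stage parameter is explicit here and overridable; thresholds default
#' to the analysis conventions used throughout the package (BH q < 0.05 for
#' differential abundance, >= 2% variance retention, top-5% loadings, 1000
#' loading permutations, stratified 10-fold outer / 5-fold x 50 inner CV,
#' 2000 bootstrap resamples). The run seed drives every stochastic stage via
#' [derive_seed()].
#'
#' @param seed run seed.
#' @param ... named overrides of any default entry.
#' @return a named list of class `run_config`.
#' @export
default_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    cohort = list(n_patients = 26, n_proteins = 500,
                  timepoints = paste0("t", 0:4), sigma_within = 0.45,
                  n_factors_true = 3, toxicity_factor_index = 1,
                  toxicity_effect = 2, frac_toxic = 17 / 26,
                  missing_rate = 0.1),
    dea = list(contrasts = list(c("t0", "t1"), c("t0", "t3"), c("t0", "t4")),
               q_threshold = 0.05),
    power = list(deltas = c(0.4, 0.7, 1.0), sigma = 0.45, alpha = 0.05,
                 m = 500, k_expected = 30, fdr_q = 0.05),
    kinetics = list(n_clusters = 3),
    factors = list(k_max = 9, retain_pct = 2, temporal = FALSE),
    toxicity = list(timepoint = "t0", top_fraction = 0.05, perm_B = 1000,
                    bootstrap_B = 2000),
    nestedcv = list(outer_folds = 10, inner_folds = 5, inner_repeats = 50,
                    top_k = 3, bootstrap_B = 1000),
    enrich = list(gmt = NULL, q_threshold = 0.01))
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    else cfg[[nm]] <- overrides[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file.
#' @return a `run_config` (for `read_config`); the path, invisibly (for
#'   `write_config`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_config: no such file: %s", path))
  raw <- yaml::read_yaml(path)
  do.call(default_config, c(list(seed = raw$seed %||% 1),
                            raw[setdiff(names(raw), "seed")]))
}

#' @rdname read_config
#' @param config a `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> differential abundance -> power ->
#' kinetics -> factorise -> toxicity -> nested CV (-> enrichment when a GMT
#' is configured) in dependency order, writing per-stage TSV/JSON outputs and
#' a provenance manifest (config hash, seed, per-stage row counts) into
#' `out_dir`. Identical config and inputs yield identical outputs and
#' manifest hashes.
#'
#' @param config a `run_config` from [default_config()] or [read_config()].
#' @param out_dir output directory (created if absent).
#' @return the manifest list, invisibly; all artefacts are on disk.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("run_pipeline: stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    res
  }

  sim <- stage("simulate", {
    cc <- do.call(cohort_config,
                  c(config$cohort, list(seed = derive_seed(config$seed, 11))))
    simulate_cohort(cc)
  })
  write_abundance(sim$abundance, file.path(out_dir, "abundance.tsv"),
                  file.path(out_dir, "metadata.tsv"))
  write_truth(sim$truth, file.path(out_dir, "truth.json"))
  manifest$stages$simulate <- list(n_samples = ncol(sim$abundance$values),
                                   n_proteins = nrow(sim$abundance$values))

  pre <- stage("preprocess", preprocess_pipeline(sim$abundance))
  manifest$stages$preprocess <- list(n_samples = ncol(pre$values),
                                     n_proteins = nrow(pre$values))

  dea <- stage("dea", {
    res <- lapply(config$dea$contrasts, function(ct)
      paired_t_contrast(pre, ct[1], ct[2]))
    names(res) <- vapply(config$dea$contrasts,
                         function(ct) paste(ct[1], ct[2], sep = "_vs_"), "")
    res
  })
  for (nm in names(dea))
    write.table(dea[[nm]], file.path(out_dir, paste0("dea_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  sets <- dap_sets(dea, config$dea$q_threshold)
  jsonlite::write_json(list(regions = sets$regions,
                            significant = lapply(sets$significant, identity)),
                       file.path(out_dir, "venn_regions.json"), auto_unbox = FALSE)
  manifest$stages$dea <- list(n_contrasts = length(dea),
                              n_significant = vapply(sets$significant, length, 0L))

  pw <- stage("power", do.call(power_table, config$power[names(config$power) %in%
    c("deltas", "sigma", "alpha", "m", "k_expected", "fdr_q")]))
  write.table(pw, file.path(out_dir, "power_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$power <- list(n_rows = nrow(pw))

  shared <- Reduce(intersect, sets$significant)
  kin <- NULL
  if (length(shared) >= config$kinetics$n_clusters) {
    kin <- stage("kinetics", kinetic_profiles(pre, shared,
                                              config$kinetics$n_clusters))
    write.table(kin, file.path(out_dir, "kinetic_clusters.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$kinetics <- list(n_proteins = nrow(kin),
                                     silhouette = attr(kin, "silhouette"))
  }

  fm <- stage("factorise", {
    m <- if (isTRUE(config$factors$temporal))
      fit_temporal_model(pre, config$factors$k_max,
                         seed = derive_seed(config$seed, 21))
    else fit_factor_model(pre, config$factors$k_max,
                          seed = derive_seed(config$seed, 21))
    retain_factors(m, config$factors$retain_pct)
  })
  write_factor_model(fm, file.path(out_dir, "factor_model"))
  manifest$stages$factorise <- list(K = fm$K,
                                    var_explained = round(fm$var_explained, 4))

  tox <- stage("toxicity", {
    tp <- toxicity_pipeline(pre, timepoint = config$toxicity$timepoint,
                            k_max = config$factors$k_max,
                            retain_pct = config$factors$retain_pct,
                            fraction = config$toxicity$top_fraction,
                            perm_B = config$toxicity$perm_B,
                            seed = derive_seed(config$seed, 31))
    scr <- toxicity_screen(fm, bootstrap_B = config$toxicity$bootstrap_B,
                           seed = derive_seed(config$seed, 32))
    Z0 <- factor_scores_at(fm, config$toxicity$timepoint)
    y0 <- pre$meta$toxicity[match(rownames(Z0), pre$meta$patient_id)]
    list(clusters = tp$clusters, fisher_p = tp$fisher$p,
         factor_tests = tp$factor_tests, best_factor = tp$factor_used,
         biomarkers = tp$biomarkers, screen = scr, Z0 = Z0, y0 = y0)
  })
  write.table(tox$biomarkers, file.path(out_dir, "biomarkers.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tox$screen, file.path(out_dir, "toxicity_screen.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$toxicity <- list(fisher_p = tox$fisher_p,
                                   best_factor = tox$best_factor,
                                   n_biomarkers = nrow(tox$biomarkers))

  ncv <- stage("nestedcv", nested_cv(tox$Z0, tox$y0,
                                     outer_folds = config$nestedcv$outer_folds,
                                     inner_folds = config$nestedcv$inner_folds,
                                     inner_repeats = config$nestedcv$inner_repeats,
                                     top_k = config$nestedcv$top_k,
                                     seed = derive_seed(config$seed, 41)))
  boot <- stage("bootstrap", bootstrap_refit_auc(
    tox$Z0[, ncv$chosen_features[[1]], drop = FALSE], tox$y0,
    B = config$nestedcv$bootstrap_B, seed = derive_seed(config$seed, 42)))
  jsonlite::write_json(list(outer_auc = ncv$outer_auc, pooled_auc = ncv$pooled_auc,
                            fold_aucs = ncv$fold_aucs,
                            selection_freq = as.list(ncv$selection_freq),
                            bootstrap_auc = boot$auc, bootstrap_ci = boot$ci),
                       file.path(out_dir, "nestedcv.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$stages$nestedcv <- list(outer_auc = ncv$outer_auc,
                                   bootstrap_auc = boot$auc)

  if (!is.null(config$enrich$gmt)) {
    lib <- read_gmt(config$enrich$gmt)
    bg <- rownames(pre$values)
    enr <- stage("enrich", ora(tox$biomarkers$protein, bg, lib,
                               q_threshold = config$enrich$q_threshold))
    write.table(enr, file.path(out_dir, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$enrich <- list(n_significant = nrow(enr))
  }

  manifest$manifest_hash <- rlang_free_hash(manifest)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# internal: dependency-free stable hash (FNV-1a over the serialised object)
rlang_free_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(raw)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

config_hash <- function(config) rlang_free_hash(unclass(config))

#' Serialise a factor model to a TSV + JSON bundle
#'
#' Writes `Z.tsv` (scores), `W.tsv` (loadings), and `model.json`
#' (variance explained, noise variance, kernel parameters when temporal).
#'
#' @param model a `factor_model`.
#' @param dir output directory prefix.
#' @return the directory, invisibly.
#' @export
write_factor_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(data.frame(sample_id = rownames(model$Z), model$Z),
              file.path(dir, "Z.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(protein_id = rownames(model$W), model$W),
              file.path(dir, "W.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  js <- list(K = model$K, var_explained = model$var_explained,
             noise_var = model$noise_var, temporal = isTRUE(model$temporal),
             converged = model$converged, iterations = model$iterations)
  if (!is.null(model$kernel_params)) js$kernel_params <- model$kernel_params
  if (!is.null(model$smoothness)) js$smoothness <- model$smoothness
  jsonlite::write_json(js, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
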