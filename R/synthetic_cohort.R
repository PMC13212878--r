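#' Configuration for a simulated longitudinal cohort
#'
#' Defaults emulate the prostate cohort of the study design this package
#' analyses: 26 patients sampled weekly at t0..t4, ~500 quantified plasma
#' proteins, within-subject log2 noise SD 0.45, 17/26 patients developing
#' late radiation-induced bowel/urinary toxicity.
#'
#' @param n_patients number of patients (>= 4).
#' @param n_proteins number of proteins (default 500).
#' @param timepoints ordered character vector of timepoint labels (>= 3).
#' @param sigma_within within-subject log2 noise SD (default 0.45).
#' @param n_factors_true number of planted latent factors.
#' @param toxicity_factor_index which factor carries the toxicity shift.
#' @param toxicity_effect Cohen's-d-scale mean shift on the toxicity factor's
#'   scores in toxic patients.
#' @param toxicity_profile `"constant"` (shift at every timepoint, default) or
#'   `"growing"` (shift ramps linearly from 0 at t0 to full size at the last
#'   timepoint).
#' @param frac_toxic proportion of toxic patients in (0, 1); default 17/26.
#' @param missing_rate proportion of intermediate patient-timepoints dropped,
#'   in `[0, 0.5)`.
#' @param intercept_sd SD of the per-(patient, protein) random intercept
#'   (log2 units, default 0.3).
#' @param loading_frac fraction of proteins loading on each factor
#'   (disjoint supports; default 0.05).
#' @param factor_scale multiplier on planted loading magnitudes; per-protein
#'   signal SD is roughly `factor_scale`, so signal-to-noise is
#'   `factor_scale / sigma_within`.
#' @param score_time_sd SD of the per-timepoint wiggle around each patient's
#'   factor level (default 0.3).
#' @param n_kinetic number of proteins given planted kinetic mean
#'   trajectories (split evenly over increasing / decreasing / nonmonotone).
#' @param kinetic_amplitude peak-to-trough size of planted trajectories
#'   (log2 units).
#' @param baseline_mean,baseline_sd log2-scale mean and SD of baseline protein
#'   means (log-normal on the linear scale, mimicking the dynamic range of
#'   plasma intensities).
#' @param cohort cohort label stored in the metadata.
#' @param seed integer seed; all randomness derives from it.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 26, n_proteins = 500,
                          timepoints = paste0("t", 0:4),
                          sigma_within = 0.45,
                          n_factors_true = 3, toxicity_factor_index = 1,
                          toxicity_effect = 1, toxicity_profile = c("constant", "growing"),
                          frac_toxic = 17 / 26, missing_rate = 0,
                          intercept_sd = 0.3, loading_frac = 0.05,
                          factor_scale = 1, score_time_sd = 0.3,
                          n_kinetic = 60, kinetic_amplitude = 1,
                          baseline_mean = 20, baseline_sd = 2,
                          cohort = "prostate", seed = 1) {
  toxicity_profile <- match.arg(toxicity_profile)
  cfg <- list(n_patients = n_patients, n_proteins = n_proteins,
              timepoints = as.character(timepoints), sigma_within = sigma_within,
              n_factors_true = n_factors_true,
              toxicity_factor_index = toxicity_factor_index,
              toxicity_effect = toxicity_effect, toxicity_profile = toxicity_profile,
              frac_toxic = frac_toxic, missing_rate = missing_rate,
              intercept_sd = intercept_sd, loading_frac = loading_frac,
              factor_scale = factor_scale, score_time_sd = score_time_sd,
              n_kinetic = n_kinetic, kinetic_amplitude = kinetic_amplitude,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              cohort = cohort, seed = seed)
  check <- function(ok, field, msg) {
    if (!ok) stop(sprintf("cohort_config: invalid '%s': %s", field, msg))
  }
  check(n_patients >= 4, "n_patients", "must be >= 4")
  check(length(cfg$timepoints) >= 3, "timepoints", "need >= 3 timepoints")
  check(!any(duplicated(cfg$timepoints)), "timepoints", "labels must be unique")
  check(sigma_within > 0, "sigma_within", "must be > 0")
  check(missing_rate >= 0 && missing_rate < 0.5, "missing_rate", "must be in [0, 0.5)")
  check(n_factors_true >= 1, "n_factors_true", "must be >= 1")
  check(toxicity_factor_index >= 1 && toxicity_factor_index <= n_factors_true,
        "toxicity_factor_index", "must index a planted factor")
  check(frac_toxic > 0 && frac_toxic < 1, "frac_toxic", "must be in (0, 1)")
  check(intercept_sd >= 0, "intercept_sd", "must be >= 0")
  check(loading_frac > 0 && loading_frac <= 1, "loading_frac", "must be in (0, 1]")
  check(n_kinetic >= 0 &&
          n_kinetic + ceiling(loading_frac * n_proteins) * n_factors_true <= n_proteins,
        "n_kinetic", "kinetic + factor-support proteins exceed n_proteins")
  structure(cfg, class = "cohort_config")
}

#' Simulate a longitudinal plasma-proteomics cohort
#'
#' Generates log2 abundances as baseline protein means (log-normal dynamic
#' range) + latent-factor signal `Z W'` + per-(patient, protein) random
#' intercept + N(0, sigma_within^2) noise, with planted kinetic mean
#' trajectories (monotone up, monotone down, non-monotone bump) on a subset
#' of proteins. Toxic patients carry a mean shift of `toxicity_effect` on the
#' toxicity factor's scores. Output is deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return list with components `abundance` (an [abundance_matrix()]), `meta`
#'   (its sample metadata), and `truth` (list: `true_scores`
#'   patient x timepoint x factor array, `true_loadings` protein x factor,
#'   `toxic_patients`, `planted_biomarkers`, `planted_kinetic_class`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  n <- cfg$n_patients; p <- cfg$n_proteins
  tps <- cfg$timepoints; Tn <- length(tps); K <- cfg$n_factors_true
  patients <- sprintf("P%02d", seq_len(n))
  proteins <- sprintf("PROT%04d", seq_len(p))

  set.seed(derive_seed(cfg$seed, 1))
  n_toxic <- round(cfg$frac_toxic * n)
  toxic <- sort(sample(n, n_toxic))
  toxicity <- as.integer(seq_len(n) %in% toxic)

  baseline <- rnorm(p, cfg$baseline_mean, cfg$baseline_sd)

  # disjoint factor supports, then kinetic proteins from the remainder
  support_size <- ceiling(cfg$loading_frac * p)
  set.seed(derive_seed(cfg$seed, 2))
  pool <- sample(p)
  supports <- split(pool[seq_len(support_size * K)],
                    rep(seq_len(K), each = support_size))
  W <- matrix(0, p, K, dimnames = list(proteins, paste0("factor", seq_len(K))))
  for (k in seq_len(K))
    W[supports[[k]], k] <- cfg$factor_scale *
      sample(c(-1, 1), support_size, replace = TRUE) * runif(support_size, 0.7, 1.3)

  kinetic_class <- character(0)
  kinetic_traj <- matrix(0, p, Tn)
  if (cfg$n_kinetic > 0) {
    remainder <- pool[-seq_len(support_size * K)]
    kin_idx <- remainder[seq_len(cfg$n_kinetic)]
    classes <- rep_len(c("increasing", "decreasing", "nonmonotone"), cfg$n_kinetic)
    s <- seq(0, 1, length.out = Tn)
    shapes <- rbind(increasing = s - 0.5,
                    decreasing = 0.5 - s,
                    nonmonotone = sin(pi * s) - mean(sin(pi * s)))
    kinetic_traj[kin_idx, ] <- cfg$kinetic_amplitude * shapes[classes, , drop = FALSE]
    kinetic_class <- setNames(classes, proteins[kin_idx])
  }

  # factor scores: patient level + per-timepoint wiggle; toxicity shift on one factor
  set.seed(derive_seed(cfg$seed, 3))
  Ztrue <- array(0, dim = c(n, Tn, K),
                 dimnames = list(patients, tps, paste0("factor", seq_len(K))))
  patient_level <- matrix(rnorm(n * K), n, K)
  for (k in seq_len(K)) {
    wiggle <- matrix(rnorm(n * Tn, sd = cfg$score_time_sd), n, Tn)
    Ztrue[, , k] <- patient_level[, k] + wiggle
  }
  kf <- cfg$toxicity_factor_index
  shift <- if (cfg$toxicity_profile == "constant") rep(1, Tn)
           else seq(0, 1, length.out = Tn)
  Ztrue[toxic, , kf] <- Ztrue[toxic, , kf] +
    rep(cfg$toxicity_effect * shift, each = length(toxic))

  # assemble abundance: samples ordered patient-major
  set.seed(derive_seed(cfg$seed, 4))
  # per-patient level offset (inter-individual / technical intensity shift;
  # the normalisation chain is designed to remove exactly this)
  intercepts <- rnorm(n, sd = cfg$intercept_sd)
  sample_ids <- as.vector(t(outer(patients, tps, paste, sep = "_")))
  values <- matrix(NA_real_, p, n * Tn, dimnames = list(proteins, sample_ids))
  col <- 0L
  for (i in seq_len(n)) {
    for (t in seq_len(Tn)) {
      col <- col + 1L
      z_it <- Ztrue[i, t, ]
      values[, col] <- baseline + kinetic_traj[, t] + drop(W %*% z_it) +
        intercepts[i] + rnorm(p, sd = cfg$sigma_within)
    }
  }
  meta <- data.frame(
    sample_id = sample_ids,
    patient_id = rep(patients, each = Tn),
    cohort = cfg$cohort,
    timepoint = rep(tps, times = n),
    toxicity = rep(toxicity, each = Tn),
    stringsAsFactors = FALSE)
  mat <- abundance_matrix(values, meta, timepoint_levels = tps, log2_scale = TRUE)

  if (cfg$missing_rate > 0)
    mat <- inject_missingness(mat, cfg$missing_rate, derive_seed(cfg$seed, 5))

  truth <- list(true_scores = Ztrue, true_loadings = W,
                toxic_patients = patients[toxic],
                planted_biomarkers = proteins[supports[[kf]]],
                planted_kinetic_class = kinetic_class)
  list(abundance = mat, meta = mat$meta, truth = truth)
}

#' Drop intermediate patient-timepoints at random
#'
#' Removes whole samples (patient-timepoint columns) uniformly at random
#' among *intermediate* timepoints only: the first and last timepoint of each
#' patient are never removed, so linear interpolation of interior gaps
#' remains well defined. Exactly `round(rate * n_eligible)` samples are
#' removed.
#'
#' @param mat an [abundance_matrix()].
#' @param rate removal rate in `[0, 0.5)`.
#' @param seed integer seed.
#' @return the matrix with removed samples dropped.
#' @export
inject_missingness <- function(mat, rate, seed) {
  stopifnot(inherits(mat, "abundance_matrix"))
  if (rate < 0 || rate >= 0.5)
    stop("inject_missingness: rate must be in [0, 0.5)")
  if (rate == 0) return(mat)
  idx <- timepoint_index(mat)
  eligible <- logical(ncol(mat$values))
  for (pid in unique(mat$meta$patient_id)) {
    sel <- mat$meta$patient_id == pid
    if (sum(sel) <= 2) next
    rng <- range(idx[sel])
    eligible[sel] <- idx[sel] > rng[1] & idx[sel] < rng[2]
  }
  n_remove <- round(rate * sum(eligible))
  if (n_remove == 0) return(mat)
  set.seed(seed)
  drop_cols <- sample(which(eligible), n_remove)
  abundance_matrix(mat$values[, -drop_cols, drop = FALSE],
                   mat$meta[-drop_cols, , drop = FALSE],
                   timepoint_levels = mat$timepoint_levels,
                   log2_scale = mat$log2_scale)
}

#' Write simulation ground truth as JSON
#'
#' @param truth the `truth` component of [simulate_cohort()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- list(
    toxic_patients = truth$toxic_patients,
    planted_biomarkers = truth$planted_biomarkers,
    planted_kinetic_class = as.list(truth$planted_kinetic_class),
    true_loadings = truth$true_loadings,
    true_scores = truth$true_scores)
  jsonlite::write_json(out, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}
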