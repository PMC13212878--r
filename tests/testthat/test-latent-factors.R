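test_that("rank-1 noiseless data is explained by the first factor", {
  set.seed(1)
  z <- rnorm(30); w <- rnorm(60)
  X <- tcrossprod(w, z)        # proteins x samples
  dimnames(X) <- list(sprintf("P%02d", 1:60), sprintf("s%02d", 1:30))
  fm <- fit_factor_model(X, 2, seed = 1)
  expect_gt(fm$var_explained[1], 99)
  # reconstruction matches the data closely
  recon <- tcrossprod(fm$W, fm$Z) + fm$center
  expect_lt(max(abs(recon - X)), 1e-2)
})

test_that("planted 3-factor loadings are recovered within 15 degrees at SNR 3", {
  angles <- vapply(1:3, function(s) {
    cc <- cohort_config(factor_scale = 1.35, n_kinetic = 0, toxicity_effect = 0,
                        intercept_sd = 0, seed = s)
    sim <- simulate_cohort(cc)
    fm <- fit_factor_model(sim$abundance, 3, seed = 1)
    max_principal_angle(sim$truth$true_loadings, fm$W)
  }, 0)
  expect_true(all(angles < 15))
})

test_that("white noise yields a weak leading factor", {
  set.seed(2)
  X <- matrix(rnorm(500 * 100), 500, 100,
              dimnames = list(sprintf("P%03d", 1:500), sprintf("s%03d", 1:100)))
  fm <- fit_factor_model(X, 1, seed = 1)
  expect_lt(fm$var_explained[1], 10)
})

test_that("variance explained is non-negative, ordered, and bounded", {
  cc <- cohort_config(n_patients = 10, n_proteins = 60, n_kinetic = 0, seed = 3)
  sim <- simulate_cohort(cc)
  fm <- fit_factor_model(preprocess_pipeline(sim$abundance), 6, seed = 1)
  expect_true(all(fm$var_explained >= 0))
  expect_lte(sum(fm$var_explained), 100)
  expect_equal(fm$var_explained, sort(fm$var_explained, decreasing = TRUE))
})

test_that("retention applies the 2% rule with a one-factor floor", {
  fake <- structure(list(Z = matrix(0, 4, 3), W = matrix(0, 5, 3),
                         var_explained = c(40, 10, 1.9), K = 3,
                         noise_var = rep(1, 5)), class = "factor_model")
  expect_equal(retain_factors(fake, 2)$K, 2)
  fake$var_explained <- c(1, 1, 1)
  expect_equal(retain_factors(fake, 2)$K, 1)      # floor rule
  fake$var_explained <- c(40, 10, 1.9)
  expect_equal(retain_factors(fake, 0)$K, 3)      # zero threshold keeps all

  # on simulated data the rule returns the planted factor count
  cc <- cohort_config(factor_scale = 1.35, n_kinetic = 0, toxicity_effect = 0,
                      intercept_sd = 0, seed = 4)
  sim <- simulate_cohort(cc)
  fm <- fit_factor_model(preprocess_pipeline(sim$abundance), 9, seed = 1)
  expect_equal(retain_factors(fm, 2)$K, 3)
})

test_that("refitting with a different seed reproduces well-separated factors", {
  cc <- cohort_config(factor_scale = 1.35, n_kinetic = 0, toxicity_effect = 0,
                      intercept_sd = 0, n_proteins = 200, n_patients = 14, seed = 5)
  sim <- simulate_cohort(cc)
  f1 <- fit_factor_model(sim$abundance, 3, seed = 1)
  f2 <- fit_factor_model(sim$abundance, 3, seed = 99)
  for (k in 1:3) expect_gt(abs(cor(f1$W[, k], f2$W[, k])), 0.95)
})

test_that("factor scores can be sliced by timepoint and partition back to Z", {
  cc <- cohort_config(n_patients = 26, n_proteins = 60, n_kinetic = 12, seed = 6)
  sim <- simulate_cohort(cc)
  fm <- fit_factor_model(suppressWarnings(preprocess_pipeline(sim$abundance)),
                         4, seed = 1)
  Z0 <- factor_scores_at(fm, "t0")
  expect_equal(nrow(Z0), 26)
  expect_setequal(rownames(Z0), unique(sim$meta$patient_id))
  stacked <- do.call(rbind, lapply(fm$timepoint_levels,
                                   function(tp) factor_scores_at(fm, tp)))
  expect_equal(unname(sort(stacked[, 1])), unname(sort(fm$Z[, 1])))
  expect_error(factor_scores_at(fm, "t9"), "available")
})

test_that("temporal model ranks a planted smooth factor as smoothest", {
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    n_pat <- 6; Tn <- 8; p <- 30
    pat <- rep(sprintf("P%02d", 1:n_pat), each = Tn)
    tp <- rep(paste0("t", 0:(Tn - 1)), n_pat)
    phase <- rep(runif(n_pat, 0, 2 * pi), each = Tn)
    z_smooth <- sin(2 * pi * rep(0:(Tn - 1), n_pat) / Tn + phase)
    z_noise <- rnorm(n_pat * Tn)
    W <- matrix(0, p, 2)
    W[1:12, 1] <- rnorm(12); W[13:24, 2] <- rnorm(12)
    X <- cbind(z_smooth, z_noise) %*% t(W) +
      matrix(rnorm(n_pat * Tn * p, sd = 0.3), n_pat * Tn, p)
    vals <- t(X)
    dimnames(vals) <- list(sprintf("PR%02d", 1:p), paste(pat, tp, sep = "_"))
    meta <- data.frame(sample_id = colnames(vals), patient_id = pat,
                       cohort = "c", timepoint = tp)
    mat <- abundance_matrix(vals, meta, timepoint_levels = paste0("t", 0:(Tn - 1)))
    tm <- fit_temporal_model(mat, 2, n_iter = 4, seed = 1)
    smooth_k <- which.max(abs(cor(tm$W, W[, 1])))
    tm$smoothness[smooth_k] > tm$smoothness[-smooth_k]
  }, TRUE)
  expect_gte(mean(wins), 0.95)
})

test_that("temporal model has a no-smoothing limit and reconstructs smooth data", {
  set.seed(7)
  n_pat <- 5; Tn <- 6; p <- 20
  pat <- rep(sprintf("P%d", 1:n_pat), each = Tn)
  tp <- rep(paste0("t", 0:(Tn - 1)), n_pat)
  z <- sin(seq(0, pi, length.out = Tn))[rep(1:Tn, n_pat)] +
    rep(rnorm(n_pat, sd = 0.3), each = Tn)
  w <- rnorm(p)
  vals <- tcrossprod(w, z)
  dimnames(vals) <- list(sprintf("PR%02d", 1:p), paste(pat, tp, sep = "_"))
  meta <- data.frame(sample_id = colnames(vals), patient_id = pat,
                     cohort = "c", timepoint = tp)
  mat <- abundance_matrix(vals, meta, timepoint_levels = paste0("t", 0:(Tn - 1)))

  base <- fit_factor_model(mat, 1, seed = 1)
  tm0 <- fit_temporal_model(mat, 1, lengthscale = 0, seed = 1)
  expect_lt(max(abs(tm0$Z - base$Z)), 1e-3)

  tm <- fit_temporal_model(mat, 1, n_iter = 4, seed = 1)
  recon <- t(tcrossprod(tm$W, tm$Z)) + rep(tm$center, each = ncol(vals))
  rel <- sqrt(sum((t(recon) - vals)^2) / sum((vals - mean(vals))^2))
  expect_lt(rel, 1e-2)

  # single timepoint falls back to the static model with a warning
  one <- subset_samples(mat, timepoints = "t0")
  expect_warning(tm1 <- fit_temporal_model(one, 1, seed = 1), "single timepoint")
  expect_false(isTRUE(tm1$temporal))
})
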