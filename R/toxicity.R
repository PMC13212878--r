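#' Hierarchically cluster patients in factor space
#'
#' Agglomerative clustering of patients on their (standardised) factor-score
#' vectors, tree cut at two clusters. Clustering is data-driven, without
#' outcome labels. Ward linkage on standardised scores by default; complete
#' linkage available.
#'
#' @param Z patients x factors score matrix (e.g. [factor_scores_at()]).
#' @param linkage `"ward"` (default) or `"complete"`.
#' @param standardise z-score each factor before clustering.
#' @return list: `clusters` (named 1/2 vector), `hclust`.
#' @export
cluster_patients <- function(Z, linkage = c("ward", "complete"), standardise = TRUE) {
  linkage <- match.arg(linkage)
  Z <- as.matrix(Z)
  if (nrow(Z) < 4) stop("cluster_patients: need >= 4 patients")
  Zs <- if (standardise) {
    sds <- apply(Z, 2, sd)
    scale(Z, scale = ifelse(sds > 0, sds, 1))
  } else Z
  hc <- hclust(dist(Zs), method = if (linkage == "ward") "ward.D2" else "complete")
  clusters <- cutree(hc, k = 2)
  names(clusters) <- rownames(Z)
  list(clusters = clusters, hclust = hc)
}

#' Fisher's exact association between clusters and toxicity
#'
#' Two-sided Fisher exact test (hypergeometric: the p-value sums the
#' probabilities of all tables with fixed margins no more probable than the
#' observed one) of the 2x2 cluster x toxicity table.
#'
#' @param clusters cluster labels (two levels).
#' @param toxicity binary outcome, aligned with `clusters`.
#' @return list: `p`, `table` (2x2), `odds_ratio` (conditional MLE).
#' @export
fisher_association <- function(clusters, toxicity) {
  stopifnot(length(clusters) == length(toxicity))
  tab <- table(cluster = factor(clusters), toxicity = factor(as.integer(as.logical(toxicity)),
                                                             levels = c(0, 1)))
  if (nrow(tab) != 2) stop("fisher_association: expected exactly two clusters")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("fisher_association: degenerate margin (all one label); p = 1")
    return(list(p = 1, table = tab, odds_ratio = NA_real_))
  }
  ft <- fisher.test(tab, alternative = "two.sided")
  list(p = ft$p.value, table = tab, odds_ratio = unname(ft$estimate))
}

#' Per-factor cluster difference with Bonferroni correction
#'
#' Welch two-sided t-test of each factor's scores between the two patient
#' clusters; adjusted p = `min(1, p * K)` over the K factors.
#'
#' @param Z patients x factors matrix.
#' @param clusters two-level cluster labels aligned with rows of `Z`.
#' @return data.frame: `factor`, `t_stat`, `p`, `p_bonf`.
#' @export
factor_cluster_difference <- function(Z, clusters) {
  Z <- as.matrix(Z)
  lev <- unique(clusters)
  if (length(lev) != 2) stop("factor_cluster_difference: expected two clusters")
  g1 <- clusters == lev[1]
  if (sum(g1) < 2 || sum(!g1) < 2)
    stop("factor_cluster_difference: each cluster needs >= 2 patients")
  K <- ncol(Z)
  res <- lapply(seq_len(K), function(k) {
    if (sd(Z[g1, k]) == 0 && sd(Z[!g1, k]) == 0) {
      tt <- list(statistic = 0, p.value = 1)
    } else tt <- t.test(Z[g1, k], Z[!g1, k], var.equal = FALSE)
    data.frame(factor = colnames(Z)[k] %||% paste0("factor", k),
               t_stat = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonf <- pmin(1, out$p * K)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Top-weight proteins of a factor
#'
#' The `ceil(fraction * n_proteins)` proteins with the largest absolute
#' loadings on one factor, ties broken by protein identifier (with a
#' warning), rank and loading sign retained.
#'
#' @param W proteins x factors loading matrix.
#' @param factor column index or name.
#' @param fraction fraction of proteins to keep, in (0, 1] (default 0.05).
#' @return data.frame: `protein`, `loading`, `rank`, `sign`.
#' @export
top_weight_proteins <- function(W, factor = 1, fraction = 0.05) {
  if (fraction <= 0 || fraction > 1)
    stop("top_weight_proteins: fraction must be in (0, 1]")
  w <- W[, factor]
  n_keep <- ceiling(fraction * length(w))
  aw <- abs(w)
  ord <- order(-aw, rownames(W))
  boundary <- aw[ord][n_keep]
  if (sum(aw == boundary) > 1 &&
      any(aw[ord][-seq_len(n_keep)] == boundary))
    warning("top_weight_proteins: ties at the selection boundary broken by protein id")
  sel <- ord[seq_len(n_keep)]
  data.frame(protein = rownames(W)[sel], loading = w[sel],
             rank = seq_len(n_keep), sign = ifelse(w[sel] >= 0, "up", "down"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Permutation null for factor loadings
#'
#' Builds a null by randomly permuting the loading values across protein
#' labels in each of `B` replicates; the empirical p-value per protein is the
#' add-one-smoothed proportion of permutations in which the permuted absolute
#' loading meets or exceeds the observed one:
#' `p = (1 + #\{|w*| >= |w_obs|\}) / (B + 1)`. Permutations are
#' fixed-point-free (a protein is never compared against its own observed
#' loading), so a protein holding the unique largest absolute loading attains
#' the floor `1 / (B + 1)`.
#'
#' @param W proteins x factors loading matrix.
#' @param factor column index or name.
#' @param B number of permutations (>= 100; default 1000).
#' @param seed integer seed.
#' @return data.frame: `protein`, `loading`, `perm_p`.
#' @export
permutation_loading_test <- function(W, factor = 1, B = 1000, seed = 1) {
  if (B < 100) stop("permutation_loading_test: B must be >= 100")
  w <- W[, factor]
  aw <- abs(w)
  n <- length(w)
  set.seed(seed)
  exceed <- integer(n)
  idx <- seq_len(n)
  for (b in seq_len(B)) {
    perm <- sample.int(n)
    fixed <- which(perm == idx)
    if (length(fixed) > 1) {
      perm[fixed] <- perm[c(fixed[-1], fixed[1])]   # rotate fixed points away
    } else if (length(fixed) == 1) {
      j <- if (fixed == 1L) 2L else 1L              # swap with another slot
      perm[c(fixed, j)] <- perm[c(j, fixed)]
    }
    exceed <- exceed + (aw[perm] >= aw)
  }
  data.frame(protein = rownames(W), loading = w,
             perm_p = (1 + exceed) / (B + 1),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Toxic vs non-toxic fold-change validation
#'
#' Mean log2 abundance difference (toxic minus non-toxic) per candidate
#' protein at one timepoint, flagged when more than two-fold in either
#' direction (strictly `|log2 FC| > 1`; a shift of exactly one log2 unit is
#' the boundary and is not flagged).
#'
#' @param mat an [abundance_matrix()] on the log2 scale with `toxicity`
#'   metadata.
#' @param timepoint timepoint label.
#' @param proteins candidate proteins (default: all).
#' @return data.frame: `protein`, `log2_fc`, `flag` in
#'   `{"up", "down", "none"}`.
#' @export
fold_change_validation <- function(mat, timepoint, proteins = rownames(mat$values)) {
  stopifnot(inherits(mat, "abundance_matrix"), "toxicity" %in% names(mat$meta))
  sel <- mat$meta$timepoint == timepoint
  tox <- mat$meta$toxicity[sel] == 1
  if (!any(tox) || all(tox))
    stop("fold_change_validation: both outcome groups must be non-empty")
  v <- mat$values[proteins, sel, drop = FALSE]
  fc <- rowMeans(v[, tox, drop = FALSE]) - rowMeans(v[, !tox, drop = FALSE])
  data.frame(protein = proteins, log2_fc = fc,
             flag = ifelse(fc > 1, "up", ifelse(fc < -1, "down", "none")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Univariable toxicity screen of one score vector
#'
#' Effect size (Cohen's d with pooled SD, classified by the conventional
#' thresholds: moderate `0.5 <= |d| < 0.8`, large `|d| >= 0.8`), two-sided
#' Mann-Whitney p (exact for <= 10 per group without ties, otherwise
#' normal approximation with tie correction), and AUC computed as
#' `U / (n1 * n0)`.
#'
#' @param values numeric scores (one factor or one protein, per patient).
#' @param toxicity binary outcome aligned with `values`.
#' @return one-row data.frame: `cohens_d`, `d_class`, `u_p`, `auc`, `n1`, `n0`.
#' @export
univariable_screen <- function(values, toxicity) {
  y <- as.integer(as.logical(toxicity))
  if (length(unique(y)) < 2) stop("univariable_screen: one-class outcome")
  x1 <- values[y == 1]; x0 <- values[y == 0]
  if (length(x1) < 2 || length(x0) < 2)
    stop("univariable_screen: need >= 2 per group")
  n1 <- length(x1); n0 <- length(x0)
  sp <- sqrt(((n1 - 1) * var(x1) + (n0 - 1) * var(x0)) / (n1 + n0 - 2))
  d <- if (sp > 0) (mean(x1) - mean(x0)) / sp else 0
  d_class <- if (abs(d) >= 0.8) "large" else if (abs(d) >= 0.5) "moderate" else "small"
  u_p <- suppressWarnings(
    wilcox.test(x1, x0, alternative = "two.sided",
                exact = (n1 <= 10 && n0 <= 10 && !any(duplicated(values))),
                correct = FALSE)$p.value)
  data.frame(cohens_d = d, d_class = d_class, u_p = u_p,
             auc = auc_rank(values, y), n1 = n1, n0 = n0,
             stringsAsFactors = FALSE)
}

#' Factor x timepoint toxicity screen
#'
#' Runs [univariable_screen()] for every retained factor at every timepoint,
#' BH-adjusting the U-test p-values across the whole screen, with optional
#' bootstrap AUC confidence intervals.
#'
#' @param model a `factor_model` fitted with metadata including `toxicity`.
#' @param bootstrap_B bootstrap resamples for the AUC CI (0 to skip).
#' @param seed seed for the bootstrap.
#' @return data.frame with one row per (factor, timepoint): effect size,
#'   `u_p`, `u_q`, `auc`, and `auc_lo`/`auc_hi` when bootstrapped.
#' @export
toxicity_screen <- function(model, bootstrap_B = 2000, seed = 1) {
  stopifnot(inherits(model, "factor_model"))
  if (is.null(model$meta) || !"toxicity" %in% names(model$meta))
    stop("toxicity_screen: model metadata lacks a toxicity label")
  tps <- intersect(model$timepoint_levels, unique(model$meta$timepoint))
  rows <- list()
  for (tp in tps) {
    sel <- model$meta$timepoint == tp
    y <- model$meta$toxicity[sel]
    for (k in seq_len(model$K)) {
      z <- model$Z[sel, k]
      row <- univariable_screen(z, y)
      row$factor <- colnames(model$Z)[k]
      row$timepoint <- tp
      if (bootstrap_B > 0) {
        ci <- bootstrap_auc_ci(z, y, B = bootstrap_B,
                               seed = derive_seed(seed, k * 131 + match(tp, tps)))
        row$auc_lo <- ci$ci[1]; row$auc_hi <- ci$ci[2]
      }
      rows[[paste(tp, k)]] <- row
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$u_q <- bh_adjust(out$u_p)
  out[, c("factor", "timepoint", "cohens_d", "d_class", "u_p", "u_q", "auc",
          intersect(c("auc_lo", "auc_hi"), names(out)), "n1", "n0")]
}

#' Bootstrap percentile confidence interval for a univariable AUC
#'
#' Patients are resampled with replacement `B` times and the AUC recomputed
#' on each resample; resamples containing a single outcome class are redrawn.
#' The CI is the empirical 2.5-97.5 percentile interval.
#'
#' @param values numeric scores per patient.
#' @param toxicity binary outcome.
#' @param B resamples (default 2000).
#' @param seed integer seed.
#' @return list: `auc` (point estimate), `ci` (length-2), `B`.
#' @export
bootstrap_auc_ci <- function(values, toxicity, B = 2000, seed = 1) {
  y <- as.integer(as.logical(toxicity))
  if (length(unique(y)) < 2) stop("bootstrap_auc_ci: both classes must be present")
  n <- length(y)
  set.seed(seed)
  aucs <- numeric(B)
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2) break
    }
    aucs[b] <- auc_rank(values[idx], y[idx])
  }
  list(auc = auc_rank(values, y),
       ci = unname(quantile(aucs, c(0.025, 0.975))), B = B)
}

#' Univariable logistic odds ratio with Wald confidence interval
#'
#' Logistic regression of the binary outcome on one predictor (fit by IRLS
#' via [stats::glm()]); the odds ratio per unit increase is `exp(slope)` with
#' 95% Wald CI `exp(slope +/- 1.96 SE)`. Perfect separation is detected and
#' reported as non-estimable rather than returning a diverged estimate.
#'
#' @param values predictor (log2 abundance or factor score).
#' @param toxicity binary outcome.
#' @return one-row data.frame: `or`, `or_lo`, `or_hi`, `slope`, `se`,
#'   `separable` (logical).
#' @export
logistic_or <- function(values, toxicity) {
  y <- as.integer(as.logical(toxicity))
  if (length(unique(y)) < 2) stop("logistic_or: both classes must be present")
  fit <- suppressWarnings(glm(y ~ values, family = binomial()))
  slope <- coef(fit)[2]
  se <- sqrt(diag(vcov(fit)))[2]
  mu <- fitted(fit)
  separable <- !fit$converged || abs(slope) > 15 ||
    all(abs(mu - y) < 1e-8)
  if (separable) {
    return(data.frame(or = NA_real_, or_lo = NA_real_, or_hi = NA_real_,
                      slope = NA_real_, se = NA_real_, separable = TRUE))
  }
  data.frame(or = exp(slope), or_lo = exp(slope - 1.96 * se),
             or_hi = exp(slope + 1.96 * se),
             slope = unname(slope), se = unname(se), separable = FALSE,
             row.names = NULL)
}

#' Baseline toxicity stratification pipeline
#'
#' The full factor-based toxicity analysis at one timepoint: factorise the
#' preprocessed data, retain factors above the variance threshold, cluster
#' patients in retained factor space, test the cluster-toxicity association
#' (Fisher exact), test per-factor cluster separation (Welch + Bonferroni),
#' and screen the top-loading proteins of the candidate factor through the
#' permutation loading test. The candidate factor defaults to the
#' top-variance retained factor (factor 1) — the primary driver of
#' variation — with the cluster-association tests reported as evidence;
#' `factor = "cluster"` instead picks the factor with the smallest
#' Bonferroni-adjusted cluster-difference p.
#'
#' @param pre a preprocessed log2 [abundance_matrix()] with `toxicity`.
#' @param timepoint timepoint at which patients are scored (default `"t0"`).
#' @param k_max factors fitted (default 9).
#' @param retain_pct variance-explained retention threshold (default 2).
#' @param fraction top-loading fraction (default 0.05).
#' @param perm_B loading permutations (default 1000).
#' @param perm_alpha permutation-p cutoff for the biomarker call (default 0.05).
#' @param factor `"top_variance"` (default), `"cluster"`, or an explicit
#'   index/name.
#' @param seed integer seed.
#' @return list: `model` (retained `factor_model`), `clusters`, `fisher`
#'   (p + table), `factor_tests`, `factor_used`, `biomarkers`
#'   (a [biomarker_records()] table), `called` (proteins passing the
#'   permutation filter).
#' @export
toxicity_pipeline <- function(pre, timepoint = "t0", k_max = 9, retain_pct = 2,
                              fraction = 0.05, perm_B = 1000, perm_alpha = 0.05,
                              factor = c("top_variance", "cluster"), seed = 1) {
  if (is.character(factor)) factor <- match.arg(factor)
  fm <- retain_factors(fit_factor_model(pre, k_max, seed = derive_seed(seed, 1)),
                       retain_pct)
  Z0 <- factor_scores_at(fm, timepoint)
  y0 <- pre$meta$toxicity[match(rownames(Z0), pre$meta$patient_id)]
  cl <- cluster_patients(Z0)
  fa <- fisher_association(cl$clusters, y0)
  fd <- factor_cluster_difference(Z0, cl$clusters)
  factor_used <- if (identical(factor, "top_variance")) colnames(fm$Z)[1]
    else if (identical(factor, "cluster")) fd$factor[which.min(fd$p_bonf)]
    else factor
  bm <- biomarker_records(pre, fm, factor = factor_used, timepoint = timepoint,
                          fraction = fraction, B = perm_B,
                          seed = derive_seed(seed, 2))
  list(model = fm, clusters = cl$clusters, fisher = fa, factor_tests = fd,
       factor_used = factor_used, biomarkers = bm,
       called = bm$protein[bm$perm_p <= perm_alpha])
}

#' Per-protein biomarker evaluation table
#'
#' For each candidate protein: its loading on the factor of interest, the
#' permutation p of that loading, the toxic vs non-toxic log2 fold change at
#' the timepoint, the logistic odds ratio per log2 unit with Wald CI, and the
#' univariable AUC.
#'
#' @param mat log2-scale [abundance_matrix()] with `toxicity` metadata.
#' @param model a `factor_model` over the same proteins.
#' @param factor factor of interest (index or name).
#' @param timepoint timepoint label for the abundance-based statistics.
#' @param fraction top-loading fraction screened (default 0.05).
#' @param B loading permutations (default 1000).
#' @param seed integer seed.
#' @return data.frame of class `biomarker_records`, one row per screened
#'   protein: `protein`, `loading`, `perm_p`, `log2_fc`, `or`, `or_lo`,
#'   `or_hi`, `auc`, `separable`.
#' @export
biomarker_records <- function(mat, model, factor = 1, timepoint,
                              fraction = 0.05, B = 1000, seed = 1) {
  stopifnot(inherits(mat, "abundance_matrix"), inherits(model, "factor_model"))
  top <- top_weight_proteins(model$W, factor, fraction)
  perm <- permutation_loading_test(model$W, factor, B = B, seed = seed)
  fc <- fold_change_validation(mat, timepoint, top$protein)
  sel <- mat$meta$timepoint == timepoint
  y <- mat$meta$toxicity[sel]
  rows <- lapply(seq_len(nrow(top)), function(i) {
    pr <- top$protein[i]
    v <- mat$values[pr, sel]
    lr <- logistic_or(v, y)
    data.frame(protein = pr, loading = top$loading[i],
               perm_p = perm$perm_p[match(pr, perm$protein)],
               log2_fc = fc$log2_fc[match(pr, fc$protein)],
               or = lr$or, or_lo = lr$or_lo, or_hi = lr$or_hi,
               auc = auc_rank(v, y), separable = lr$separable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("biomarker_records", class(out))
  out
}
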