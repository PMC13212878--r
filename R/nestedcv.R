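#' Nested cross-validation with stability-based feature selection
#'
#' Outer stratified k-fold CV estimates out-of-sample AUC; all feature
#' selection happens inside each outer-training partition via repeated
#' stratified inner CV (5-fold x 50 repetitions by default): every candidate
#' feature is scored by univariable AUC on the inner validation folds, the
#' per-split top features are tallied into a selection frequency, and the
#' features passing the selection rule enter a ridge-penalised logistic model
#' trained on the outer-training set and scored on the held-out fold, which
#' is never touched during selection or training.
#'
#' @param features patients x features matrix (complete).
#' @param outcome binary outcome per patient.
#' @param outer_folds outer fold count (default 10; capped at the smaller
#'   class size with a warning).
#' @param inner_folds inner fold count (default 5).
#' @param inner_repeats inner repetitions (default 50).
#' @param select_rule `"top_k"` (default) or `"threshold"`.
#' @param top_k features entering the model under the top-k rule (default 3).
#' @param auc_threshold inner mean-AUC cutoff under the threshold rule
#'   (default 0.6).
#' @param lambda ridge penalty of the outer logistic model.
#' @param seed integer seed; all fold assignments derive from it.
#' @param outcome_eval labels used only for outer-fold evaluation (defaults
#'   to `outcome`; supplying a different vector audits leakage — selection
#'   and training are unaffected by it).
#' @return list of class `nested_cv_result`: `outer_auc` (mean of per-fold
#'   AUCs), `pooled_auc` (AUC of pooled out-of-fold predictions),
#'   `fold_aucs`, `selection_freq` (per feature, over all inner iterations of
#'   all outer folds), `chosen_features` (per outer fold), `fold_ids`,
#'   `stability_band` (per feature: `>= 0.8` highly reproducible, `>= 0.5`
#'   moderately stable, else unstable), and the geometry used.
#' @export
nested_cv <- function(features, outcome, outer_folds = 10, inner_folds = 5,
                      inner_repeats = 50, select_rule = c("top_k", "threshold"),
                      top_k = 3, auc_threshold = 0.6, lambda = 1e-2, seed = 1,
                      outcome_eval = outcome) {
  select_rule <- match.arg(select_rule)
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.integer(as.logical(outcome))
  y_eval <- as.integer(as.logical(outcome_eval))
  if (anyNA(X)) stop("nested_cv: features must be complete")
  stopifnot(length(y) == nrow(X), length(y_eval) == nrow(X))
  fold_ids <- stratified_folds(y, outer_folds, derive_seed(seed, 1))
  k_out <- max(fold_ids)
  feat <- colnames(X)
  sel_count <- setNames(numeric(ncol(X)), feat)
  n_inner_iter <- 0
  fold_aucs <- rep(NA_real_, k_out)
  chosen <- vector("list", k_out)
  oof_pred <- rep(NA_real_, nrow(X))

  for (fo in seq_len(k_out)) {
    tr <- which(fold_ids != fo)
    te <- which(fold_ids == fo)
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    inner_auc_sum <- setNames(numeric(ncol(X)), feat)
    # one inner iteration = one repeat of the k-fold CV: each feature is
    # scored by its mean validation AUC over that repeat's folds, and the
    # selection rule is applied per repeat
    for (rep_i in seq_len(inner_repeats)) {
      in_folds <- stratified_folds(ytr, inner_folds,
                                   derive_seed(seed, 1000 * fo + rep_i))
      k_in <- max(in_folds)
      rep_auc <- setNames(numeric(ncol(X)), feat)
      rep_n <- 0
      for (fi in seq_len(k_in)) {
        val <- in_folds == fi
        yv <- ytr[val]
        if (length(unique(yv)) < 2) next
        aucs <- apply(Xtr[val, , drop = FALSE], 2, function(v) {
          a <- auc_rank(v, yv); max(a, 1 - a)   # direction-free discrimination
        })
        rep_auc <- rep_auc + aucs
        rep_n <- rep_n + 1
      }
      if (rep_n == 0) next
      rep_auc <- rep_auc / rep_n
      n_inner_iter <- n_inner_iter + 1
      picked <- if (select_rule == "top_k") {
        feat[order(-rep_auc, feat)][seq_len(min(top_k, length(feat)))]
      } else feat[rep_auc >= auc_threshold]
      sel_count[picked] <- sel_count[picked] + 1
      inner_auc_sum <- inner_auc_sum + rep_auc
    }
    mean_auc <- inner_auc_sum / inner_repeats
    chosen[[fo]] <- if (select_rule == "top_k") {
      feat[order(-mean_auc, feat)][seq_len(min(top_k, length(feat)))]
    } else {
      sel <- feat[mean_auc >= auc_threshold]
      if (!length(sel)) feat[which.max(mean_auc)] else sel
    }
    fit <- ridge_logistic(Xtr[, chosen[[fo]], drop = FALSE], ytr, lambda = lambda)
    pred <- ridge_logistic_predict(fit, X[te, chosen[[fo]], drop = FALSE])
    oof_pred[te] <- pred
    if (length(unique(y_eval[te])) == 2)
      fold_aucs[fo] <- auc_rank(pred, y_eval[te])
  }
  selection_freq <- sel_count / max(n_inner_iter, 1)
  band <- ifelse(selection_freq >= 0.8, "highly_reproducible",
                 ifelse(selection_freq >= 0.5, "moderately_stable", "unstable"))
  structure(list(
    outer_auc = mean(fold_aucs, na.rm = TRUE),
    pooled_auc = auc_rank(oof_pred, y_eval),
    fold_aucs = fold_aucs,
    selection_freq = selection_freq,
    stability_band = band,
    chosen_features = chosen,
    fold_ids = fold_ids,
    geometry = list(outer_folds = k_out, inner_folds = inner_folds,
                    inner_repeats = inner_repeats, select_rule = select_rule,
                    top_k = top_k, auc_threshold = auc_threshold,
                    lambda = lambda, seed = seed)),
    class = "nested_cv_result")
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat(sprintf("nested_cv_result: outer AUC %.3f (pooled %.3f) over %d folds\n",
              x$outer_auc, x$pooled_auc, x$geometry$outer_folds))
  top <- sort(x$selection_freq, decreasing = TRUE)
  cat("  top selection frequencies:",
      paste(sprintf("%s=%.2f", names(head(top, 3)), head(top, 3)), collapse = " "), "\n")
  invisible(x)
}

#' Composite feature ranking
#'
#' Combines predictive strength, statistical significance, and selection
#' stability into one score: the mean of min-max-normalised AUC, -log10 p,
#' and selection frequency. Ranking is descending; ties break by feature
#' identifier.
#'
#' @param auc per-feature AUC.
#' @param p_value per-feature p-value.
#' @param stability per-feature selection frequency.
#' @param weights optional length-3 weights (default equal).
#' @return data.frame: `feature`, `score`, `rank`, sorted by rank.
#' @export
composite_rank <- function(auc, p_value, stability, weights = c(1, 1, 1) / 3) {
  if (length(auc) != length(p_value) || length(auc) != length(stability))
    stop("composite_rank: component vectors must have equal length")
  feat <- names(auc) %||% paste0("f", seq_along(auc))
  minmax <- function(v) {
    r <- range(v)
    if (diff(r) == 0) rep(0.5, length(v)) else (v - r[1]) / diff(r)
  }
  comp <- cbind(minmax(auc), minmax(-log10(pmax(p_value, 1e-300))), minmax(stability))
  score <- drop(comp %*% (weights / sum(weights)))
  if (anyDuplicated(score))
    warning("composite_rank: tied scores broken by feature identifier")
  ord <- order(-score, feat)
  data.frame(feature = feat[ord], score = score[ord],
             rank = seq_along(score), stringsAsFactors = FALSE, row.names = NULL)
}

#' Bootstrap refit AUC (apparent, optimism-prone)
#'
#' Resamples patients with replacement, refits the ridge logistic model on
#' each resample, and computes the apparent (in-sample) AUC on that resample;
#' the percentile interval quantifies variability of the in-sample signal,
#' not generalisable performance — flagged as optimism-prone in the output.
#'
#' @param features patients x features matrix.
#' @param outcome binary outcome.
#' @param B resamples (default 1000).
#' @param lambda ridge penalty.
#' @param seed integer seed.
#' @return list: `auc` (full-data apparent AUC), `ci` (2.5/97.5 percentiles),
#'   `B`, `optimism_prone = TRUE`.
#' @export
bootstrap_refit_auc <- function(features, outcome, B = 1000, lambda = 1e-2, seed = 1) {
  X <- as.matrix(features)
  y <- as.integer(as.logical(outcome))
  if (length(unique(y)) < 2) stop("bootstrap_refit_auc: both classes must be present")
  n <- length(y)
  set.seed(derive_seed(seed, 7))
  aucs <- numeric(B)
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2) break
    }
    fit <- ridge_logistic(X[idx, , drop = FALSE], y[idx], lambda = lambda)
    aucs[b] <- auc_rank(ridge_logistic_predict(fit, X[idx, , drop = FALSE]), y[idx])
  }
  full <- ridge_logistic(X, y, lambda = lambda)
  list(auc = auc_rank(ridge_logistic_predict(full, X), y),
       ci = unname(quantile(aucs, c(0.025, 0.975))),
       B = B, optimism_prone = TRUE)
}
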