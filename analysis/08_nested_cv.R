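#!/usr/bin/env Rscript
# Unbiased predictive performance of the retained baseline factors:
# stratified nested cross-validation (outer 10-fold capped by class size;
# inner 5-fold x 50 repeats with top-3 selection), composite feature
# ranking, and the optimism-prone bootstrap refit AUC for contrast.

library(radtox)
dir.create("results/nestedcv", showWarnings = FALSE, recursive = TRUE)

pre <- read_abundance("results/preprocessed/prostate_zscored.tsv",
                      "results/preprocessed/prostate_metadata.tsv")
fm <- retain_factors(fit_factor_model(pre, 9, seed = 1), 2)
Z0 <- factor_scores_at(fm, "t0")
y0 <- pre$meta$toxicity[match(rownames(Z0), pre$meta$patient_id)]

ncv <- suppressWarnings(nested_cv(Z0, y0, outer_folds = 10, inner_folds = 5,
                                  inner_repeats = 50, seed = 13))
scr <- vapply(colnames(Z0), function(k) {
  r <- univariable_screen(Z0[, k], y0); c(r$auc, r$u_p)
}, c(0, 0))
rank <- composite_rank(pmax(scr[1, ], 1 - scr[1, ]), scr[2, ],
                       ncv$selection_freq[colnames(Z0)])
boot <- bootstrap_refit_auc(Z0[, ncv$chosen_features[[1]], drop = FALSE], y0,
                            B = 1000, seed = 17)

jsonlite::write_json(list(outer_auc = ncv$outer_auc, pooled_auc = ncv$pooled_auc,
                          fold_aucs = ncv$fold_aucs,
                          selection_freq = as.list(ncv$selection_freq),
                          stability_band = as.list(ncv$stability_band),
                          bootstrap_auc = boot$auc, bootstrap_ci = boot$ci),
                     "results/nestedcv/summary.json", auto_unbox = TRUE, digits = NA)
write.table(rank, "results/nestedcv/composite_rank.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("nested-CV outer AUC %.3f (pooled %.3f); bootstrap refit AUC %.2f [%.2f, %.2f]\n",
            ncv$outer_auc, ncv$pooled_auc, boot$auc, boot$ci[1], boot$ci[2]))
cat("composite ranking:\n"); print(rank, row.names = FALSE)
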