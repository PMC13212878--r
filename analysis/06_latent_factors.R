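#!/usr/bin/env Rscript
# Latent factor models of the prostate cohort: the static EM factor analysis
# with the >= 2% variance retention rule, and the temporal model with
# GP-smoothed factor scores (15 factors, per-factor smoothness).

library(radtox)
dir.create("results/factors", showWarnings = FALSE, recursive = TRUE)

pre <- read_abundance("results/preprocessed/prostate_zscored.tsv",
                      "results/preprocessed/prostate_metadata.tsv")

fm <- retain_factors(fit_factor_model(pre, 9, seed = 1), 2)
write_factor_model(fm, "results/factors/static")
cat(sprintf("static model: %d/9 factors retained at >= 2%%; var explained: %s\n",
            fm$K, paste(sprintf("%.1f", fm$var_explained), collapse = " ")))

tm <- fit_temporal_model(pre, 15, seed = 1)
write_factor_model(tm, "results/factors/temporal")
cat("temporal model smoothness (top 5 factors):",
    sprintf("%.2f", head(tm$smoothness, 5)), "\n")
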