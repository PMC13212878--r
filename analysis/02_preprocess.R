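#!/usr/bin/env Rscript
# Missing-data and normalisation chain per cohort: linear interpolation of
# intermediate missing timepoints (measured endpoints untouched), quantile
# normalisation across samples, then per-protein z-scoring.

library(radtox)
dir.create("results/preprocessed", showWarnings = FALSE, recursive = TRUE)

for (nm in c("prostate", "bladder", "head_neck")) {
  mat <- read_abundance(file.path("results/data", paste0(nm, "_abundance.tsv")),
                        file.path("results/data", paste0(nm, "_metadata.tsv")))
  pre <- preprocess_pipeline(mat)
  write_abundance(pre,
                  file.path("results/preprocessed", paste0(nm, "_zscored.tsv")),
                  file.path("results/preprocessed", paste0(nm, "_metadata.tsv")))
  cat(sprintf("%-9s: %d x %d complete after interpolation\n",
              nm, nrow(pre$values), ncol(pre$values)))
}
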