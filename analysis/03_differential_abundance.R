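#!/usr/bin/env Rscript
# Paired differential abundance per cohort at the three study contrasts
# (t0 vs t1, t0 vs t3, t0 vs t_end), BH-adjusted per contrast, with the
# shared/unique DAP set algebra across contrasts (the Venn regions).

library(radtox)
dir.create("results/dea", showWarnings = FALSE, recursive = TRUE)

for (nm in c("prostate", "bladder", "head_neck")) {
  pre <- read_abundance(file.path("results/preprocessed", paste0(nm, "_zscored.tsv")),
                        file.path("results/preprocessed", paste0(nm, "_metadata.tsv")))
  t_end <- tail(pre$timepoint_levels, 1)
  contrasts <- list(c("t0", "t1"), c("t0", "t3"), c("t0", t_end))
  res <- lapply(contrasts, function(ct) paired_t_contrast(pre, ct[1], ct[2]))
  names(res) <- vapply(contrasts, function(ct) paste(ct, collapse = "_vs_"), "")
  for (cn in names(res))
    write.table(res[[cn]], file.path("results/dea", paste0(nm, "_", cn, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  sets <- dap_sets(res, q_threshold = 0.05)
  jsonlite::write_json(list(regions = sets$regions),
                       file.path("results/dea", paste0(nm, "_venn.json")),
                       auto_unbox = TRUE, digits = NA)
  cat(sprintf("%-9s DAPs (q<0.05): %s; shared across all contrasts: %d\n", nm,
              paste(vapply(sets$significant, length, 0L), collapse = "/"),
              length(Reduce(intersect, sets$significant))))
}
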