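#!/usr/bin/env Rscript
# Kinetic clustering of the longitudinally shared DAPs per cohort: mean
# trajectories across patients, correlation-as-features complete-linkage
# clustering into three clusters, silhouette quality, archetype labels.

library(radtox)
dir.create("results/kinetics", showWarnings = FALSE, recursive = TRUE)

for (nm in c("prostate", "bladder", "head_neck")) {
  pre <- read_abundance(file.path("results/preprocessed", paste0(nm, "_zscored.tsv")),
                        file.path("results/preprocessed", paste0(nm, "_metadata.tsv")))
  files <- list.files("results/dea", pattern = paste0("^", nm, "_t0_vs"), full.names = TRUE)
  sig <- lapply(files, function(f) { d <- read.delim(f); d$protein[d$q < 0.05] })
  shared <- Reduce(intersect, sig)
  if (length(shared) < 6) { cat(nm, ": fewer than 6 shared DAPs, skipped\n"); next }
  prof <- kinetic_profiles(pre, shared, n_clusters = 3)
  write.table(prof, file.path("results/kinetics", paste0(nm, "_clusters.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%-9s: %d shared DAPs, silhouette %.2f, archetypes: %s\n", nm,
              length(shared), attr(prof, "silhouette"),
              paste(names(table(prof$archetype)), table(prof$archetype),
                    collapse = " ", sep = "=")))
}
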