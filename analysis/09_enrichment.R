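#!/usr/bin/env Rscript
# Local over-representation analysis of the called biomarkers against a
# SYNTHETIC gene-set library (constructed here: one set enriched for planted
# biomarkers plus random sets), Fisher exact with BH adjustment. The library
# is synthetic stand-in content, not a curated ontology.

library(radtox)
dir.create("results/enrichment", showWarnings = FALSE, recursive = TRUE)
set.seed(19)

bm <- read.delim("results/toxicity/biomarkers_t0.tsv")
pre <- read_abundance("results/preprocessed/prostate_zscored.tsv",
                      "results/preprocessed/prostate_metadata.tsv")
background <- rownames(pre$values)
truth <- jsonlite::read_json("results/data/prostate_truth.json",
                             simplifyVector = TRUE)

sets <- c(list(planted_toxicity_module =
                 unique(c(truth$planted_biomarkers, sample(background, 10)))),
          setNames(lapply(1:15, function(i) sample(background, 25)),
                   paste0("random_set_", 1:15)))
write_gmt(sets, "results/enrichment/synthetic_sets.gmt")

lib <- read_gmt("results/enrichment/synthetic_sets.gmt")
res <- ora(bm$protein[bm$perm_p <= 0.05], background, lib, q_threshold = 0.01)
write.table(attr(res, "all"), "results/enrichment/ora_all.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("%d/%d sets pass q < 0.01\n", nrow(res), length(lib$sets)))
print(res[, c("set", "overlap_count", "odds_ratio", "p", "q")], row.names = FALSE)
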