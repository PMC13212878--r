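#!/usr/bin/env Rscript
# Simulate the three radiotherapy cohorts (prostate, bladder, head & neck)
# with the study's design: weekly sampling t0-t4 (t0-t6 for head & neck),
# ~500 quantified plasma proteins, within-subject log2 noise SD 0.45, three
# planted latent factors with the first carrying the late-toxicity signal,
# and 10% intermediate-timepoint missingness. Ground truth is kept for the
# recovery analyses downstream.

library(radtox)
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
seed <- 20260927

cohorts <- list(
  prostate  = cohort_config(n_patients = 26, timepoints = paste0("t", 0:4),
                            frac_toxic = 17 / 26, toxicity_effect = 2,
                            missing_rate = 0.1, cohort = "prostate",
                            seed = derive_seed(seed, 1)),
  bladder   = cohort_config(n_patients = 23, timepoints = paste0("t", 0:4),
                            frac_toxic = 0.5, toxicity_effect = 0,
                            missing_rate = 0.1, cohort = "bladder",
                            seed = derive_seed(seed, 2)),
  head_neck = cohort_config(n_patients = 11, timepoints = paste0("t", 0:6),
                            frac_toxic = 0.5, toxicity_effect = 0,
                            missing_rate = 0.1, cohort = "head_neck",
                            seed = derive_seed(seed, 3)))

for (nm in names(cohorts)) {
  sim <- simulate_cohort(cohorts[[nm]])
  write_abundance(sim$abundance,
                  file.path("results/data", paste0(nm, "_abundance.tsv")),
                  file.path("results/data", paste0(nm, "_metadata.tsv")))
  write_truth(sim$truth, file.path("results/data", paste0(nm, "_truth.json")))
  cat(sprintf("%-9s: %d patients, %d samples, %d proteins, %d toxic\n",
              nm, length(unique(sim$meta$patient_id)), nrow(sim$meta),
              nrow(sim$abundance$values), length(sim$truth$toxic_patients)))
}
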