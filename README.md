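# radtox

Longitudinal plasma-proteomics analysis of radiotherapy response and late
toxicity, as a tested R package plus a numbered analysis workflow.

## The problem

Radiotherapy triggers a systemic response visible in the circulating
proteome. Weekly plasma sampling before and during treatment (baseline `t0`,
then `t1`, `t2`, ... up to the final fraction) across prostate, bladder, and
head & neck cancer cohorts raises a chain of statistical questions this
package implements end to end:

1. **Paired differential abundance** — which proteins change between
   timepoints within patients? Paired t-tests on log2 intensities with
   Benjamini–Hochberg FDR control, repeated-measures ANOVA across the full
   time course, and shared/unique set algebra across contrasts.
2. **Power under multiplicity** — what effect sizes can each cohort detect?
   Exact two-sided paired-t power via the noncentral t distribution,
   `ncp = (δ/σ)√n`, evaluated at the nominal α, the BH-effective
   α (`(k/m)·q`), and the Bonferroni bound, with the within-subject SD
   σ ≈ 0.45 log2 units.
3. **Kinetic clustering** — what trajectory shapes do the shared proteins
   follow? Complete-linkage clustering of correlation-matrix rows, silhouette
   quality, and monotone/non-monotone archetype labels.
4. **Latent factor modelling** — what coordinated axes of variation span the
   proteome? A Gaussian factor model `x = Wz + ε` fitted by EM with
   per-protein noise, varimax-resolved rotation, the ≥2 % variance-explained
   retention rule, and a longitudinal extension with squared-exponential
   Gaussian-process priors smoothing each factor's per-patient score
   trajectory.
5. **Toxicity stratification** — do the factors predict late radiation-induced
   bowel/urinary toxicity? Ward clustering of patients in factor space,
   Fisher's exact cluster–outcome association, top-5 % loading selection with
   a 1000-permutation loading null, two-fold-change validation, per-protein
   odds ratios (Wald CIs) and AUCs with 2000-resample bootstrap CIs.
6. **Honest predictive performance** — stratified nested cross-validation
   (10-fold outer, 5-fold × 50 inner with stability selection), composite
   feature ranking, and the optimism-prone bootstrap refit AUC for contrast.
7. **Over-representation analysis** — Fisher/hypergeometric enrichment of
   protein lists against GMT gene-set libraries, locally.

Because the study's raw data live in a proteomics repository, the package
ships a **synthetic cohort generator** that emulates the design (cohort
sizes 26/23/11, weekly sampling, ~500 proteins, σ = 0.45, planted latent
factors tied to a binary toxicity label, intermediate-timepoint missingness)
with full ground truth, so every stage is validated by parameter recovery.

## Worked example

```r
library(radtox)

cfg  <- cohort_config(n_patients = 26, frac_toxic = 17/26,
                      toxicity_effect = 2, missing_rate = 0.1, seed = 1)
sim  <- simulate_cohort(cfg)
pre  <- preprocess_pipeline(sim$abundance)   # interpolate -> quantile -> z-score
tox  <- toxicity_pipeline(pre, timepoint = "t0", perm_B = 1000, seed = 7)

tox$factor_used
#> [1] "factor1"
length(tox$called)                            # proteins passing the permutation filter
#> [1] 25
mean(tox$called %in% sim$truth$planted_biomarkers)
#> [1] 1
```

Twenty-five of the 25 planted toxicity biomarkers (top-5 % loadings of the
primary factor, permutation p ≤ 0.05) are recovered with precision 1.00.
Running the numbered drivers reproduces the full analysis:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

which prints, among others (seed fixed in the scripts):

```
prostate  DAPs (q<0.05): 37/61/42; shared across all contrasts: 11
prostate : 11 shared DAPs, silhouette 0.76, archetypes: decreasing=6 increasing=5
static model: 5/9 factors retained at >= 2%; var explained: 5.8 4.9 4.8 3.9 2.6
biomarkers called (perm p <= 0.05): 25; precision 1.00, recall 1.00 vs planted
nested-CV outer AUC 0.778 (pooled 0.843); bootstrap refit AUC 0.93 [0.82, 1.00]
```

and writes the tables under `results/`.

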