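---
title: "Longitudinal plasma proteomics of radiotherapy response: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal plasma proteomics of radiotherapy response: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radtox)
```

This vignette is the package's own account of the statistical machinery it
implements: the models and their assumptions, the tunable parameters and why
their defaults are what they are, what the synthetic cohort generator does
and does not emulate, and the numerical choices made where the design was
genuinely open.

## The data model

The central object is an `abundance_matrix`: a proteins × samples grid of
log2 intensities with per-sample metadata (patient, cohort, timepoint,
optional binary late-toxicity label). Timepoints are an ordered label set
(`t0` = baseline before the first fraction, then weekly `t1`, `t2`, ...);
each patient contributes at most one sample per timepoint.

## The synthetic cohort generator

`simulate_cohort()` draws

$$x_{jit} = \mu_j + k_j(t) + \mathbf{w}_j^\top \mathbf{z}_{it} + b_i + \varepsilon_{jit},
\qquad \varepsilon_{jit} \sim N(0, \sigma^2_w),$$

for protein $j$, patient $i$, timepoint $t$, on the log2 scale:

* **Baseline means** $\mu_j \sim N(20, 2^2)$ log2 units — log-normal on the
  linear scale, mimicking the orders-of-magnitude dynamic range of plasma
  intensities.
* **Within-subject noise** $\sigma_w = 0.45$ log2 units by default, the
  empirical within-subject SD scale of normalised plasma proteomics.
* **Latent factors**: `n_factors_true` (default 3) factors with disjoint
  sparse supports (`loading_frac`, default 5 % of proteins each) and weights
  of magnitude `factor_scale` × U(0.7, 1.3) with random sign. Scores are a
  patient-level draw $a_{ik} \sim N(0,1)$ plus per-timepoint wiggle
  (SD `score_time_sd` = 0.3). Per loaded protein the signal SD is roughly
  `factor_scale`, so the per-protein signal-to-noise ratio is
  `factor_scale / sigma_within`.
* **Toxicity**: `round(frac_toxic · n)` patients (default 17/26, the
  prostate-cohort rate) carry a mean shift of `toxicity_effect` (Cohen's-d
  units) on one factor's scores — constant over time by default, optionally
  ramping linearly from zero (`toxicity_profile = "growing"`). The shifted
  factor's support is the set of planted biomarkers.
* **Patient intercept** $b_i \sim N(0, 0.3^2)$: a *per-patient scalar* level
  offset shifting all proteins of that patient equally. This is exactly the
  sample-level intensity artefact the normalisation chain is designed to
  remove. Protein-specific inter-individual structure is represented by the
  latent factors themselves, not by the intercept.
* **Kinetic classes**: `n_kinetic` proteins (default 60, outside the factor
  supports) receive planted mean trajectories — monotone up, monotone down,
  or a mid-treatment bump — of amplitude `kinetic_amplitude` (1 log2 unit).
* **Missingness**: `inject_missingness()` drops whole intermediate
  patient-timepoints uniformly at random; the first and last timepoint of a
  patient are never dropped, so interior linear interpolation stays defined.

What the generator does **not** emulate: peptide-level quantification and
roll-up, identification-level FDR, non-Gaussian heavy-tailed noise,
batch/run-order effects, informative (outcome-dependent) missingness, and
protein-specific inter-individual baselines. Passing recovery tests
therefore demonstrate correctness of the estimators under the stated
generative model, not robustness to everything real data can do.

All randomness derives from one seed through `derive_seed(seed, stream)`,
so stages are decoupled and bit-reproducible.

## Preprocessing

The chain is **interpolate → quantile normalise → log2/z-score**, in that
order; TIC normalisation, when used, acts first on linear-scale intensities
(log2 applied after — the order is configurable because the upstream
convention is ambiguous).

* `interpolate_missing()` fills only *interior* gaps of each patient's
  per-protein time course, linearly on the integer timepoint index (weekly
  spacing). Measured endpoints are never altered; missing endpoints are
  never invented; proteins missing everywhere are dropped.
* `quantile_normalise()` (via `limma::normalizeQuantiles`) forces every
  sample onto the mean sorted vector, removing sample-level intensity
  differences.
* `log2_and_zscore()` centres and scales each protein to mean 0, SD 1.
  Zero-variance proteins are kept as all-zero rows (with a warning) so the
  protein universe is identical across contrasts.

Each step is idempotent on its own output. The full chain is *not* exactly
idempotent: z-scoring re-weights rows and thereby perturbs the
equal-column-distribution property quantile normalisation establishes, so a
second pass changes values; the tests assert the per-step fixed points,
which are the true invariants.

## Differential abundance

`paired_t_contrast()` uses a complete-case design: only patients with both
timepoints enter, and the same pairs are used for every protein — so
`n_pairs` is constant within a contrast. The primary fold change is the
mean paired log2 difference; the linear-scale ratio-of-means (`fc_ratio`,
the vendor-tool convention) is reported alongside. Degenerate rows follow a
documented convention: all-zero differences give p = 1, constant non-zero
differences give the smallest representable double. BH adjustment is per
contrast, not pooled. `rm_anova()` computes the one-way within-subject
F-statistic vectorised across proteins (validated against `stats::aov` with
a patient error stratum in the tests).

## Power analysis

Exact two-sided power: with $\mathrm{ncp} = (\delta/\sigma)\sqrt{n}$ and
$df = n-1$,
$$\mathrm{power} = P\!\left(T'_{df,\mathrm{ncp}} < -t_{1-\alpha/2}\right) +
P\!\left(T'_{df,\mathrm{ncp}} > t_{1-\alpha/2}\right),$$
counting both rejection tails (at δ = 0 this returns exactly α). The
BH-effective per-test threshold at rank $k$ of $m$ is $(k/m)\,q$; for
m = 400–600 and k ≈ 30 at q = 0.05 this gives 0.0025–0.00375. (A narrative
range of 0.001–0.002 circulates for the same setting; it does not follow
from the step-up formula, and the package reports the formula's value.)

```{r power}
power_table(deltas = c(0.4, 1.0))[1:6, ]
```

## Kinetic clustering

Mean trajectories (per-timepoint average over patients) are z-scored
(shape, not level — a flag disables this), correlated, and each protein is
represented by its **row of the correlation matrix**; complete-linkage
agglomeration with Euclidean distance on those rows is the stated metric's
only consistent reading ("Euclidean" needs feature vectors, not a
similarity). The 1 − r dissimilarity alternative sits behind
`distance = "one_minus_r"`. The silhouette is computed in the same feature
space used for clustering. Archetypes: *increasing* if every successive
difference is ≥ −tol and the net change is positive (tol defaults to 5 % of
the trajectory's range), *decreasing* symmetrically, else *nonmonotone*.

## Latent factor model

`fit_factor_model()` is Gaussian factor analysis,
$x \sim N(Wz, \Psi)$ with $z \sim N(0, I_K)$ and diagonal per-protein
noise $\Psi$, fitted by EM to a relative log-likelihood tolerance of 1e-6
(cap 2000 iterations), initialised from the SVD with a small seeded jitter.
This is a re-implementation of the model *class* behind multi-omics factor
analysis — single view, Gaussian likelihood — not a port of its variational
scheme; acceptance is parameter recovery, not numeric parity. Automatic
relevance pruning is deliberately omitted: truncation is handled solely by
the ≥ 2 % variance-explained rule (`retain_factors()`, which always keeps at
least one factor) or the K = 15 cap of the temporal model.

Three reporting conventions resolve the model's indeterminacies:

* **Rotation** — the likelihood is invariant to orthogonal rotation of
  $(W, Z)$, so a varimax rotation of the loadings (the same rotation applied
  to the scores) is used to land on the sparse representative of the
  equivalence class. This is what makes refits reproducible factor-by-factor
  and planted sparse factors recoverable as individual factors.
* **Order** — factors are ordered greedily by incremental variance
  explained, $100\,(1 - SS_{res}(1..k)/SS_{tot})$ increments, so the
  cumulative curve is non-decreasing.
* **Sign** — each loading column is flipped so its largest-magnitude entry
  is positive.

The subspace-recovery experiments fit the log2-scale matrix directly: the
model estimates per-protein noise natively, whereas z-scoring first would
inflate pure-noise proteins to unit variance and put a ~22° statistical
floor on the achievable principal angle at these dimensions (n ≈ 130,
m = 500) regardless of estimator. Z-scored input is still the default for
the *pipeline*, where comparability across proteins matters more than
per-factor geometry.

## Temporal factor model

`fit_temporal_model()` alternates (i) an EM-style score update given
loadings and noise, (ii) Gaussian-process regression smoothing of each
factor's per-patient score trajectory under a squared-exponential kernel,
and (iii) a ridge-penalised least-squares loading update. Kernel
hyperparameters — lengthscale from {0.75, 1.5, 3, 6} timepoint-index units
and signal fraction from {0.1, ..., 0.999} — are chosen per factor by the
summed per-patient log marginal likelihood. The per-factor *smoothness*
statistic is the share of raw score variance captured by the smoothed
component; a planted sinusoidal factor scores near 1, white noise near 0.
A fixed lengthscale ≤ 1e-8 disables smoothing and reproduces the static EM
fit exactly (the no-smoothing limit); a single-timepoint input falls back
to the static model with a warning.

## Toxicity stratification

`toxicity_pipeline()` mirrors the analysis sequence: factorise, retain,
Ward-cluster patients on standardised retained factor scores (complete
linkage optional), Fisher's exact test of the cluster × toxicity table,
Welch t per factor with Bonferroni over factors, then the top-5 % absolute
loadings of the **candidate factor** through a 1000-permutation loading
null. The candidate defaults to the top-variance factor — the primary
driver of variation, which is also what an analyst would select — because
on 26-patient cohorts the first Ward split need not align with a single
factor's d ≈ 2 separation, making cluster-difference selection unstable;
the `factor = "cluster"` mode is available and the cluster association is
always reported as evidence.

Permutation p-values use add-one smoothing, $p = (1 + \#\{|w^*| \ge
|w|\})/(B+1)$, so the floor is $1/(B+1)$ and downstream $-\log_{10}$ plots
never see zero. Permutations are fixed-point-free (a protein never meets
its own observed loading), which makes the floor attainable by a unique
maximum. "Two-fold" validation is strict: $|\mathrm{log2FC}| > 1$, the
boundary excluded. Univariable screening reports Cohen's d with pooled SD
(moderate 0.5 ≤ |d| < 0.8, large |d| ≥ 0.8), a two-sided Mann–Whitney p
(exact for ≤ 10 per group without ties), and AUC as $U/(n_1 n_0)$.
Bootstrap AUC CIs resample patients (2000 draws, 2.5–97.5 percentiles;
one-class resamples redrawn). Logistic odds ratios come from `stats::glm`
with Wald CIs; perfect separation is flagged as non-estimable rather than
silently diverging.

## Nested cross-validation

The outer loop is stratified k-fold (default 10, capped at the smaller
class size with a warning); held-out folds are never touched during
selection or training. Within each outer-training partition, repeated
stratified CV (5-fold × 50 repeats) scores every candidate feature by its
mean validation AUC per repeat — one repeat is one selection *iteration*,
which keeps tiny validation folds from deciding by tie-break — and the
top-3 features per repeat are tallied into the selection frequency
(threshold mode, AUC ≥ 0.6, is available). Stability bands: ≥ 0.8 highly
reproducible, ≥ 0.5 moderately stable, else unstable — named bands with
package-chosen cut-offs. The outer model is a ridge-penalised logistic
regression (small fixed λ = 0.01, intercept unpenalised) because tiny
stratified folds routinely separate perfectly. The composite ranking is the
mean of min–max-normalised AUC, −log10 p, and selection frequency —
a documented default, configurable by weights.

`bootstrap_refit_auc()` is deliberately the *optimism-prone* counterpart:
refit on each patient-level resample, apparent AUC on that resample,
percentile CI — flagged as in-sample in its output. Its CI tracks the
apparent AUC, not generalisation performance; on null features it centres
well above 0.5, which is exactly the optimism the nested CV exists to
avoid, and the tests assert the directional ordering (nested outer AUC ≤
bootstrap refit AUC on average).

## Over-representation analysis

One-sided Fisher enrichment of a query list against GMT sets, computed as
the hypergeometric upper tail over the *quantified* background — the
assayed panel is a biased universe, so defaulting to the genome would
overstate enrichment. Odds ratios are cross-product with a Haldane 0.5
correction on zero cells; BH adjustment runs across all sets tested and
results are reported at q < 0.01 (the unfiltered table travels as an
attribute).

## Problem sizes used by the test suite

Simulation-backed tests run at sizes chosen to make their statistical
claims sharp while keeping the suite snappy: type-I error on 2000 null
proteins; BH false-discovery proportion over 50 × 1000 uniform p-values;
Fisher-vs-enumeration on every 2×2 table with n ≤ 12 (1,820 tables) plus
300 random tables up to n = 30; subspace recovery on three 26-patient ×
500-protein cohorts at SNR 3; smooth-factor identification over 50
replicates of 6 patients × 8 timepoints × 30 proteins; end-to-end biomarker
recovery over 20 seeds of the full 26 × 500 design; and nested-CV null
calibration over 50 replicates of 100 balanced patients × 9 factors, where
the outer-AUC sampling SD (~0.07) makes the [0.35, 0.65] band a ≥ 90 %
event. The 100-patient choice reflects that the band is a property of the
estimator, not of any one cohort size; at 26 patients the same estimator is
unbiased but noisier.

## Known limitations

* The factor model is single-view Gaussian; count-like or heavy-tailed
  views are out of scope.
* Varimax resolves rotation toward sparsity; genuinely dense, equal-variance
  factors remain identifiable only up to rotation.
* GP hyperparameters come from a small grid, not continuous optimisation;
  lengthscales between grid points are rounded to the nearest candidate.
* The generator's missingness is completely at random; informative dropout
  would bias the interpolation step in ways these tests do not probe.
* With ~26 patients, Fisher association p-values for a d = 2 factor are
  frequently non-significant even when biomarker recovery is perfect — an
  honest reflection of the design's power, not a pipeline defect.
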