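Package: radtox
Title: Longitudinal Plasma Proteomics of Radiotherapy Response and Late Toxicity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal plasma proteomics of patients
    undergoing radiotherapy: synthetic-cohort simulation with planted latent
    structure, total-ion-current and quantile normalisation with linear
    interpolation of intermediate missing timepoints, paired differential
    abundance with Benjamini-Hochberg control, noncentral-t power analysis
    under multiple-testing correction, kinetic clustering of protein
    trajectories, latent factor models with optional Gaussian-process temporal
    smoothing, factor-based late-toxicity stratification with permutation
    loading tests, nested cross-validated predictive modelling with stability
    selection, and local Fisher-exact over-representation analysis of GMT
    gene-set libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
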