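#' Total-ion-current normalisation
#'
#' Scales each sample (column) of a linear-scale intensity matrix so that its
#' total intensity equals the grand mean of per-sample totals. After scaling,
#' all column sums are equal to relative tolerance 1e-9.
#'
#' @param mat an [abundance_matrix()] on the linear scale, nonnegative values.
#' @return the normalised matrix (still linear scale).
#' @export
tic_normalise <- function(mat) {
  stopifnot(inherits(mat, "abundance_matrix"))
  if (mat$log2_scale)
    stop("tic_normalise: expects linear-scale intensities (log2_scale = FALSE)")
  v <- mat$values
  if (any(v < 0, na.rm = TRUE)) stop("tic_normalise: negative intensities")
  totals <- colSums(v, na.rm = TRUE)
  zero <- totals == 0
  if (any(zero))
    stop(sprintf("tic_normalise: zero total intensity in sample(s): %s",
                 paste(colnames(v)[zero], collapse = ", ")))
  target <- mean(totals)
  mat$values <- sweep(v, 2, target / totals, `*`)
  mat
}

#' Linear interpolation of intermediate missing timepoints
#'
#' Fills interior gaps in each patient's per-protein time course by linear
#' interpolation on the (equally spaced, weekly) timepoint index. Measured
#' endpoints are never altered and missing endpoints are never imputed.
#' Samples dropped entirely (e.g. by [inject_missingness()]) are restored as
#' interpolated columns where they are interior to the patient's observed
#' range. Proteins missing at every timepoint are dropped. Patient-protein
#' series with fewer than two observations are left missing and reported in
#' the `"unfilled"` attribute.
#'
#' @param mat an [abundance_matrix()].
#' @return an `abundance_matrix` on the full per-patient grid, with attribute
#'   `"unfilled"` (data.frame of patient/protein series left incomplete; zero
#'   rows when everything interior was filled).
#' @export
interpolate_missing <- function(mat) {
  stopifnot(inherits(mat, "abundance_matrix"))
  tps <- mat$timepoint_levels
  Tn <- length(tps)
  patients <- unique(mat$meta$patient_id)
  proteins <- rownames(mat$values)

  # expand to the full patient x timepoint grid, NA where a sample is absent
  grid_ids <- as.vector(t(outer(patients, tps, paste, sep = "_")))
  full <- matrix(NA_real_, nrow(mat$values), length(grid_ids),
                 dimnames = list(proteins, grid_ids))
  obs_grid_id <- paste(mat$meta$patient_id, mat$meta$timepoint, sep = "_")
  full[, match(obs_grid_id, grid_ids)] <- mat$values

  unfilled <- list()
  for (i in seq_along(patients)) {
    cols <- (i - 1L) * Tn + seq_len(Tn)
    block <- full[, cols, drop = FALSE]
    n_obs <- rowSums(!is.na(block))
    fill <- which(n_obs >= 2 & n_obs < Tn)
    for (r in fill) {
      y <- block[r, ]
      ok <- which(!is.na(y))
      # interior gaps only: approx with rule = 1 leaves ends NA
      filled <- approx(ok, y[ok], xout = seq_len(Tn), method = "linear", rule = 1)$y
      gap <- is.na(y) & !is.na(filled)
      block[r, gap] <- filled[gap]
    }
    short <- which(n_obs > 0 & n_obs < 2)
    if (length(short))
      unfilled[[patients[i]]] <- data.frame(patient_id = patients[i],
                                            protein_id = proteins[short],
                                            stringsAsFactors = FALSE)
    full[, cols] <- block
  }

  all_missing <- rowSums(!is.na(full)) == 0
  if (any(all_missing)) {
    warning(sprintf("interpolate_missing: dropping %d protein(s) missing at every timepoint",
                    sum(all_missing)))
    full <- full[!all_missing, , drop = FALSE]
  }
  keep_cols <- colSums(!is.na(full)) > 0
  full <- full[, keep_cols, drop = FALSE]

  pat_of <- rep(patients, each = Tn)[keep_cols]
  tp_of <- rep(tps, times = length(patients))[keep_cols]
  first <- match(pat_of, mat$meta$patient_id)
  meta <- data.frame(sample_id = colnames(full),
                     patient_id = pat_of,
                     cohort = mat$meta$cohort[first],
                     timepoint = tp_of,
                     stringsAsFactors = FALSE)
  if ("toxicity" %in% names(mat$meta)) meta$toxicity <- mat$meta$toxicity[first]
  out <- abundance_matrix(full, meta, timepoint_levels = tps,
                          log2_scale = mat$log2_scale)
  attr(out, "unfilled") <- if (length(unfilled)) do.call(rbind, unfilled)
    else data.frame(patient_id = character(0), protein_id = character(0))
  out
}

#' Quantile normalisation across samples
#'
#' Forces every sample to share the same value distribution: the sorted
#' values of each column are replaced by the row-wise mean of the sorted
#' columns (via [limma::normalizeQuantiles()]). Requires a complete matrix;
#' run [interpolate_missing()] first.
#'
#' @param mat a complete [abundance_matrix()].
#' @return the normalised matrix.
#' @export
quantile_normalise <- function(mat) {
  stopifnot(inherits(mat, "abundance_matrix"))
  if (anyNA(mat$values))
    stop("quantile_normalise: matrix has missing values; run interpolate_missing() first")
  mat$values <- limma::normalizeQuantiles(mat$values)
  mat
}

#' Log2 transform (if needed) and per-protein z-scoring
#'
#' Applies log2 when the matrix is flagged linear-scale, then centres and
#' scales each protein to mean 0, SD 1 across samples. Zero-variance proteins
#' are set to all-zero with a warning (kept, so the protein universe matches
#' across contrasts).
#'
#' @param mat an [abundance_matrix()].
#' @return the z-scored matrix (flagged log2-scale).
#' @export
log2_and_zscore <- function(mat) {
  stopifnot(inherits(mat, "abundance_matrix"))
  v <- mat$values
  if (!mat$log2_scale) {
    if (any(v <= 0, na.rm = TRUE))
      stop("log2_and_zscore: non-positive values cannot be log2-transformed")
    v <- log2(v)
  }
  mu <- rowMeans(v, na.rm = TRUE)
  sdv <- apply(v, 1, sd, na.rm = TRUE)
  flat <- sdv == 0 | is.na(sdv)
  if (any(flat)) {
    warning(sprintf("log2_and_zscore: %d zero-variance protein(s) set to zero", sum(flat)))
    sdv[flat] <- 1
  }
  z <- (v - mu) / sdv
  z[flat, ] <- 0
  mat$values <- z
  mat$log2_scale <- TRUE
  mat
}

#' Missing-data and normalisation pipeline
#'
#' Runs the chain interpolate -> quantile normalise -> log2/z-score (the
#' order used for the factor-model analyses). TIC normalisation, when
#' requested, is applied first on linear-scale input.
#'
#' @param mat an [abundance_matrix()].
#' @param tic apply [tic_normalise()] first (linear-scale input only).
#' @return the processed matrix.
#' @export
preprocess_pipeline <- function(mat, tic = FALSE) {
  if (tic) mat <- tic_normalise(mat)
  mat <- interpolate_missing(mat)
  mat <- quantile_normalise(mat)
  log2_and_zscore(mat)
}
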