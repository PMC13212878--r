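#' Construct an abundance matrix with per-sample metadata
#'
#' The pipeline's central container: a protein x sample grid of log2 (or
#' linear) intensities plus per-sample metadata. Timepoints are drawn from an
#' ordered label set (`t0`, `t1`, ...); each (patient, timepoint) pair appears
#' at most once.
#'
#' @param values numeric matrix, proteins in rows, samples in columns; row
#'   and column names required.
#' @param meta data.frame with columns `sample_id`, `patient_id`, `cohort`,
#'   `timepoint`, and optionally `toxicity` (0/1).
#' @param timepoint_levels ordered character vector of valid timepoint labels;
#'   defaults to the sorted labels present.
#' @param log2_scale logical flag; `TRUE` if `values` are log2 intensities.
#' @return an object of class `abundance_matrix`: list with `values`, `meta`,
#'   `timepoint_levels`, `log2_scale`.
#' @export
abundance_matrix <- function(values, meta, timepoint_levels = NULL, log2_scale = TRUE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("abundance_matrix: values must have protein rownames and sample colnames")
  req <- c("sample_id", "patient_id", "cohort", "timepoint")
  missing_cols <- setdiff(req, names(meta))
  if (length(missing_cols))
    stop(sprintf("abundance_matrix: metadata missing column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!setequal(colnames(values), meta$sample_id))
    stop("abundance_matrix: sample columns and metadata sample_id disagree")
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (is.null(timepoint_levels)) {
    timepoint_levels <- sort(unique(as.character(meta$timepoint)))
  }
  bad_tp <- setdiff(unique(as.character(meta$timepoint)), timepoint_levels)
  if (length(bad_tp))
    stop(sprintf("abundance_matrix: unknown timepoint label(s): %s",
                 paste(bad_tp, collapse = ", ")))
  dup <- duplicated(meta[, c("patient_id", "timepoint")])
  if (any(dup))
    stop(sprintf("abundance_matrix: duplicate (patient, timepoint) pair(s): %s",
                 paste(unique(paste(meta$patient_id[dup], meta$timepoint[dup])), collapse = ", ")))
  structure(
    list(values = values, meta = meta,
         timepoint_levels = timepoint_levels, log2_scale = isTRUE(log2_scale)),
    class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d proteins x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values),
              if (x$log2_scale) "log2" else "linear"))
  cat(sprintf("  patients: %d, timepoints: %s\n",
              length(unique(x$meta$patient_id)),
              paste(x$timepoint_levels, collapse = " ")))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

# internal: integer index (0-based) of each sample's timepoint
timepoint_index <- function(mat) {
  match(as.character(mat$meta$timepoint), mat$timepoint_levels) - 1L
}

#' Subset an abundance matrix by sample or timepoint
#'
#' @param mat an [abundance_matrix()].
#' @param sample_ids sample identifiers to keep.
#' @param timepoints alternatively, timepoint labels to keep.
#' @return the subsetted `abundance_matrix`.
#' @export
subset_samples <- function(mat, sample_ids = NULL, timepoints = NULL) {
  stopifnot(inherits(mat, "abundance_matrix"))
  if (is.null(sample_ids)) {
    if (is.null(timepoints)) stop("subset_samples: give sample_ids or timepoints")
    sample_ids <- mat$meta$sample_id[mat$meta$timepoint %in% timepoints]
  }
  keep <- match(sample_ids, colnames(mat$values))
  if (anyNA(keep)) stop("subset_samples: unknown sample id(s)")
  abundance_matrix(mat$values[, keep, drop = FALSE],
                   mat$meta[keep, , drop = FALSE],
                   timepoint_levels = mat$timepoint_levels,
                   log2_scale = mat$log2_scale)
}

#' Write an abundance matrix as long-format TSV plus metadata TSV
#'
#' @param mat `abundance_matrix`.
#' @param path output path for the long table (columns `sample_id`,
#'   `protein_id`, `log2_intensity` or `intensity`).
#' @param meta_path output path for the metadata table.
#' @return invisibly, the two paths.
#' @export
write_abundance <- function(mat, path, meta_path) {
  stopifnot(inherits(mat, "abundance_matrix"))
  value_col <- if (mat$log2_scale) "log2_intensity" else "intensity"
  long <- data.frame(
    sample_id = rep(colnames(mat$values), each = nrow(mat$values)),
    protein_id = rep(rownames(mat$values), times = ncol(mat$values)),
    value = as.vector(mat$values),
    stringsAsFactors = FALSE)
  names(long)[3] <- value_col
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(mat$meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, meta_path))
}

#' Read an abundance matrix from long-format TSV plus metadata TSV
#'
#' @param path long-format table with columns `sample_id`, `protein_id`, and
#'   `log2_intensity` (or `intensity` for linear-scale data).
#' @param meta_path metadata table (`sample_id`, `patient_id`, `cohort`,
#'   `timepoint`, optional `toxicity`).
#' @param timepoint_levels optional ordered label set; unknown labels are
#'   rejected.
#' @return an `abundance_matrix`.
#' @export
read_abundance <- function(path, meta_path, timepoint_levels = NULL) {
  if (!file.exists(path)) stop(sprintf("read_abundance: no such file: %s", path))
  if (!file.exists(meta_path)) stop(sprintf("read_abundance: no such file: %s", meta_path))
  long <- read.delim(path, stringsAsFactors = FALSE)
  for (col in c("sample_id", "protein_id"))
    if (!col %in% names(long))
      stop(sprintf("read_abundance: abundance table missing column '%s'", col))
  value_col <- intersect(c("log2_intensity", "intensity"), names(long))
  if (!length(value_col))
    stop("read_abundance: abundance table missing column 'log2_intensity' (or 'intensity')")
  value_col <- value_col[1]
  if (any(duplicated(long[, c("sample_id", "protein_id")])))
    stop("read_abundance: duplicate (sample, protein) entries")
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  proteins <- sort(unique(long$protein_id))
  samples <- meta$sample_id
  values <- matrix(NA_real_, nrow = length(proteins), ncol = length(samples),
                   dimnames = list(proteins, samples))
  values[cbind(match(long$protein_id, proteins), match(long$sample_id, samples))] <-
    long[[value_col]]
  abundance_matrix(values, meta, timepoint_levels = timepoint_levels,
                   log2_scale = value_col == "log2_intensity")
}
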