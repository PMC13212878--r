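#' Paired differential abundance between two timepoints
#'
#' Within-subject paired t-test per protein between timepoints `t_a` and
#' `t_b`. Only patients with both timepoints are used, and the same complete
#' set of pairs is used for every protein. Fold change is the mean paired
#' log2 difference (`t_b - t_a`); the linear-scale ratio-of-means fold change
#' (the vendor-tool convention) is reported alongside as `fc_ratio`.
#'
#' @param mat an [abundance_matrix()] on the log2 scale.
#' @param t_a,t_b timepoint labels (contrast is `t_b - t_a`).
#' @return data.frame of class `dea_result`: `protein`, `log2_fc`, `fc_ratio`,
#'   `t_stat`, `p`, `q` (BH), `n_pairs`, `direction`.
#' @export
paired_t_contrast <- function(mat, t_a, t_b) {
  stopifnot(inherits(mat, "abundance_matrix"))
  for (tp in c(t_a, t_b))
    if (!tp %in% mat$timepoint_levels)
      stop(sprintf("paired_t_contrast: unknown timepoint '%s'", tp))
  meta <- mat$meta
  pats_a <- meta$patient_id[meta$timepoint == t_a]
  pats_b <- meta$patient_id[meta$timepoint == t_b]
  complete <- intersect(pats_a, pats_b)
  n_pairs <- length(complete)
  if (n_pairs < 2)
    stop("paired_t_contrast: fewer than 2 patients with both timepoints")
  col_a <- meta$sample_id[meta$timepoint == t_a][match(complete, pats_a)]
  col_b <- meta$sample_id[meta$timepoint == t_b][match(complete, pats_b)]
  A <- mat$values[, col_a, drop = FALSE]
  B <- mat$values[, col_b, drop = FALSE]
  D <- B - A
  m <- rowMeans(D)
  s <- apply(D, 1, sd)
  df <- n_pairs - 1
  t_stat <- ifelse(s > 0, m / (s / sqrt(n_pairs)), ifelse(m == 0, 0, Inf * sign(m)))
  p <- 2 * pt(abs(t_stat), df, lower.tail = FALSE)
  # degenerate rows: all-zero differences -> p = 1; constant nonzero -> smallest representable
  p[s == 0 & m == 0] <- 1
  p[s == 0 & m != 0] <- .Machine$double.xmin
  fc_ratio <- rowMeans(2^B) / rowMeans(2^A)
  out <- data.frame(protein = rownames(mat$values),
                    log2_fc = m, fc_ratio = fc_ratio,
                    t_stat = t_stat, p = p, q = bh_adjust(p),
                    n_pairs = n_pairs,
                    direction = ifelse(m >= 0, "up", "down"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "contrast") <- c(t_a = t_a, t_b = t_b)
  class(out) <- c("dea_result", class(out))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted q-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("bh_adjust: p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' One-way repeated-measures ANOVA per protein
#'
#' Within-subject one-way RM-ANOVA over the listed timepoints, complete cases
#' only (patients lacking any listed timepoint are excluded from every
#' protein; the excluded count is attached as an attribute). Proteins with
#' all timepoints identical within every patient return `F = 0`, `p = 1`.
#'
#' @param mat an [abundance_matrix()].
#' @param timepoints timepoint labels to include (default: all levels).
#' @return data.frame `protein`, `f_stat`, `df1`, `df2`, `p`, with attribute
#'   `"n_excluded"`.
#' @export
rm_anova <- function(mat, timepoints = mat$timepoint_levels) {
  stopifnot(inherits(mat, "abundance_matrix"))
  meta <- mat$meta
  keep <- meta$timepoint %in% timepoints
  tab <- table(meta$patient_id[keep])
  complete <- names(tab)[tab == length(timepoints)]
  n_excluded <- length(unique(meta$patient_id)) - length(complete)
  n <- length(complete); Tn <- length(timepoints)
  if (n < 2) stop("rm_anova: fewer than 2 complete patients")
  # protein x patient x timepoint array
  cols <- lapply(timepoints, function(tp) {
    sel <- meta$timepoint == tp & meta$patient_id %in% complete
    meta$sample_id[sel][match(complete, meta$patient_id[sel])]
  })
  X <- array(NA_real_, c(nrow(mat$values), n, Tn))
  for (t in seq_len(Tn)) X[, , t] <- mat$values[, cols[[t]]]
  grand <- apply(X, 1, mean)
  subj_mean <- apply(X, c(1, 2), mean)   # protein x patient
  time_mean <- apply(X, c(1, 3), mean)   # protein x timepoint
  ss_time <- n * rowSums((time_mean - grand)^2)
  resid <- X - array(subj_mean, c(dim(subj_mean), Tn)) -
    aperm(array(time_mean, c(nrow(X), Tn, n)), c(1, 3, 2)) + grand
  ss_err <- apply(resid^2, 1, sum)
  df1 <- Tn - 1
  df2 <- (n - 1) * (Tn - 1)
  f_stat <- (ss_time / df1) / (ss_err / df2)
  p <- pf(f_stat, df1, df2, lower.tail = FALSE)
  degen <- ss_time < 1e-24 # all timepoints identical (per patient) convention
  f_stat[degen] <- 0
  p[degen | is.na(p)] <- 1
  out <- data.frame(protein = rownames(mat$values), f_stat = f_stat,
                    df1 = df1, df2 = df2, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Significant-set algebra across contrasts (Venn regions)
#'
#' Computes per-contrast significant protein sets at a BH q threshold, plus
#' the count and membership of every Venn region (each combination of
#' presence/absence across contrasts).
#'
#' @param results named list of `dea_result` data.frames sharing one protein
#'   universe.
#' @param q_threshold significance threshold on `q` (default 0.05).
#' @return list: `significant` (named list of protein sets), `regions`
#'   (data.frame with one row per nonempty region: contrast membership
#'   pattern, count), `members` (list of region member vectors), and
#'   `directions` (per contrast, named direction vector of significant
#'   proteins).
#' @export
dap_sets <- function(results, q_threshold = 0.05) {
  stopifnot(is.list(results), length(results) >= 1)
  if (is.null(names(results)) || any(names(results) == ""))
    stop("dap_sets: results must be a named list")
  universe <- results[[1]]$protein
  for (r in results)
    if (!setequal(r$protein, universe))
      stop("dap_sets: contrasts do not share a protein universe")
  sig <- lapply(results, function(r) r$protein[r$q < q_threshold])
  directions <- lapply(results, function(r) {
    s <- r$q < q_threshold
    setNames(r$direction[s], r$protein[s])
  })
  k <- length(results)
  membership <- sapply(sig, function(s) universe %in% s)
  if (k == 1) membership <- matrix(membership, ncol = 1,
                                   dimnames = list(NULL, names(results)))
  pattern <- apply(membership, 1, function(r) paste(as.integer(r), collapse = ""))
  in_any <- rowSums(membership) > 0
  regions <- list(); members <- list()
  for (pat in sort(unique(pattern[in_any]), decreasing = TRUE)) {
    sel <- pattern == pat
    lab <- paste(names(results)[strsplit(pat, "")[[1]] == "1"], collapse = "&")
    regions[[lab]] <- data.frame(region = lab, pattern = pat, count = sum(sel),
                                 stringsAsFactors = FALSE)
    members[[lab]] <- universe[sel]
  }
  regions <- if (length(regions)) do.call(rbind, c(regions, make.row.names = FALSE))
    else data.frame(region = character(0), pattern = character(0), count = integer(0))
  list(significant = sig, regions = regions, members = members,
       directions = directions)
}
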