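#' Mean abundance trajectories across patients
#'
#' Per-protein, per-timepoint mean abundance averaged over all patients with
#' a sample at that timepoint.
#'
#' @param mat an [abundance_matrix()].
#' @param protein_set proteins to profile (default: all).
#' @return matrix of mean trajectories, proteins x timepoints.
#' @export
mean_trajectories <- function(mat, protein_set = rownames(mat$values)) {
  stopifnot(inherits(mat, "abundance_matrix"))
  if (!length(protein_set)) stop("mean_trajectories: empty protein set")
  missing_p <- setdiff(protein_set, rownames(mat$values))
  if (length(missing_p))
    stop(sprintf("mean_trajectories: protein(s) not in matrix: %s",
                 paste(head(missing_p, 5), collapse = ", ")))
  tps <- mat$timepoint_levels
  out <- sapply(tps, function(tp) {
    cols <- mat$meta$sample_id[mat$meta$timepoint == tp]
    rowMeans(mat$values[protein_set, cols, drop = FALSE], na.rm = TRUE)
  })
  matrix(out, nrow = length(protein_set),
         dimnames = list(protein_set, tps))
}

#' Cluster protein trajectories via their correlation structure
#'
#' Pairwise Pearson correlations between protein mean trajectories are
#' computed; each protein is then represented by its row of the correlation
#' matrix (correlation-as-features) and clustered by complete-linkage
#' agglomeration with Euclidean distance, with the tree cut at `n_clusters`.
#' The silhouette score is computed in the same feature space. Trajectories
#' are z-scored before correlation by default (shape, not level); constant
#' trajectories have undefined correlation and are excluded with a warning.
#'
#' @param profiles matrix of mean trajectories (proteins x timepoints), e.g.
#'   from [mean_trajectories()].
#' @param n_clusters number of clusters (default 3).
#' @param scale_profiles z-score each trajectory before correlating.
#' @param distance `"euclidean"` (default; Euclidean between correlation-matrix
#'   rows) or `"one_minus_r"` (1 - r dissimilarity).
#' @return list: `labels` (named cluster vector), `hclust` (dendrogram),
#'   `silhouette` (mean silhouette width), `sil_widths` (per protein),
#'   `excluded` (constant trajectories).
#' @export
correlation_cluster <- function(profiles, n_clusters = 3, scale_profiles = TRUE,
                                distance = c("euclidean", "one_minus_r")) {
  distance <- match.arg(distance)
  stopifnot(is.matrix(profiles), ncol(profiles) >= 3)
  sds <- apply(profiles, 1, sd)
  excluded <- rownames(profiles)[sds == 0]
  if (length(excluded)) {
    warning(sprintf("correlation_cluster: excluding %d constant trajectorie(s)",
                    length(excluded)))
    profiles <- profiles[sds > 0, , drop = FALSE]
  }
  if (nrow(profiles) < n_clusters)
    stop("correlation_cluster: fewer usable profiles than clusters")
  if (scale_profiles)
    profiles <- t(scale(t(profiles)))
  C <- cor(t(profiles))
  if (distance == "euclidean") {
    d <- dist(C)          # Euclidean distance between correlation-matrix rows
    feature_space <- C
  } else {
    d <- as.dist(1 - C)
    feature_space <- NULL
  }
  hc <- hclust(d, method = "complete")
  labels <- cutree(hc, k = n_clusters)
  sil <- cluster::silhouette(labels, d)
  widths <- if (is.matrix(sil)) sil[, "sil_width"] else rep(0, length(labels))
  list(labels = labels, hclust = hc,
       silhouette = mean(widths),
       sil_widths = setNames(widths, names(labels)),
       feature_space = feature_space, excluded = excluded)
}

#' Classify a mean trajectory as increasing, decreasing, or nonmonotone
#'
#' Increasing: every successive difference is `>= -tol` and the net change is
#' positive; decreasing symmetric; anything else is nonmonotone. The default
#' tolerance is 5% of the trajectory's range, so small counter-movements do
#' not break monotonicity.
#'
#' @param means numeric trajectory (>= 3 timepoints).
#' @param tol absolute tolerance; default `0.05 * diff(range(means))`.
#' @return one of `"increasing"`, `"decreasing"`, `"nonmonotone"`.
#' @export
classify_archetype <- function(means, tol = NULL) {
  stopifnot(length(means) >= 3)
  if (is.null(tol)) tol <- 0.05 * diff(range(means))
  d <- diff(means)
  net <- means[length(means)] - means[1]
  if (all(d >= -tol) && net > 0) return("increasing")
  if (all(d <= tol) && net < 0) return("decreasing")
  "nonmonotone"
}

#' Kinetic profiles: trajectories, clusters, archetypes
#'
#' Convenience wrapper running [mean_trajectories()], [correlation_cluster()],
#' and [classify_archetype()] for a protein set.
#'
#' @inheritParams mean_trajectories
#' @inheritParams correlation_cluster
#' @return data.frame: `protein`, per-timepoint means, `cluster`, `archetype`.
#' @export
kinetic_profiles <- function(mat, protein_set = rownames(mat$values),
                             n_clusters = 3, scale_profiles = TRUE) {
  traj <- mean_trajectories(mat, protein_set)
  cl <- correlation_cluster(traj, n_clusters, scale_profiles = scale_profiles)
  keep <- setdiff(rownames(traj), cl$excluded)
  out <- data.frame(protein = keep, traj[keep, , drop = FALSE],
                    cluster = cl$labels[keep],
                    archetype = apply(traj[keep, , drop = FALSE], 1, classify_archetype),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "silhouette") <- cl$silhouette
  out
}
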