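# shared fixtures and independent oracles

# small abundance matrix built by hand: p proteins x (patients x timepoints)
make_matrix <- function(values, patients, timepoints, proteins = NULL,
                        toxicity = NULL, log2_scale = TRUE) {
  n <- length(patients); Tn <- length(timepoints)
  if (is.null(proteins)) proteins <- sprintf("PR%02d", seq_len(nrow(values)))
  sample_ids <- as.vector(t(outer(patients, timepoints, paste, sep = "_")))
  stopifnot(ncol(values) == n * Tn)
  dimnames(values) <- list(proteins, sample_ids)
  meta <- data.frame(sample_id = sample_ids,
                     patient_id = rep(patients, each = Tn),
                     cohort = "test",
                     timepoint = rep(timepoints, times = n),
                     stringsAsFactors = FALSE)
  if (!is.null(toxicity)) meta$toxicity <- rep(toxicity, each = Tn)
  abundance_matrix(values, meta, timepoint_levels = timepoints,
                   log2_scale = log2_scale)
}

# brute-force silhouette: s_i = (b_i - a_i) / max(a_i, b_i)
silhouette_brute <- function(labels, D) {
  D <- as.matrix(D)
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(D[i, labels == cl]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# brute-force two-sided Fisher exact p by hypergeometric enumeration:
# sum of probabilities of all tables with the observed margins whose
# probability is <= that of the observed table
fisher_enum <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + cc; n <- a + b + cc + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force AUC: probability a random positive exceeds a random negative
auc_brute <- function(x, y) {
  pos <- x[y == 1]; neg <- x[y == 0]
  g <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(g)
}

# reference archetype classification on integer step patterns
archetype_ref <- function(v, tol) {
  d <- diff(v)
  if (all(d >= -tol) && v[length(v)] > v[1]) "increasing"
  else if (all(d <= tol) && v[length(v)] < v[1]) "decreasing"
  else "nonmonotone"
}

# max principal angle (degrees) between loading subspaces
max_principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  max(acos(pmin(svd(crossprod(qa, qb))$d, 1)) * 180 / pi)
}

# small planted-archetype trajectory set for kinetic clustering
make_archetype_profiles <- function(n_per = 20, Tn = 5, noise = 0.05, seed = 1) {
  set.seed(seed)
  s <- seq(0, 1, length.out = Tn)
  shapes <- rbind(up = s, down = 1 - s, bump = sin(pi * s))
  lab <- rep(rownames(shapes), each = n_per)
  prof <- shapes[lab, ] + matrix(rnorm(3 * n_per * Tn, sd = noise), ncol = Tn)
  rownames(prof) <- sprintf("P%03d", seq_len(nrow(prof)))
  list(profiles = prof, labels = lab)
}
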