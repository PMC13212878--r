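#' Fit a Gaussian latent factor model by expectation-maximisation
#'
#' Probabilistic factor analysis of a complete (preprocessed) abundance
#' matrix: samples are modelled as `x = W z + eps` with `z ~ N(0, I_K)` and
#' per-protein residual variance `eps_j ~ N(0, psi_j)`. Fitting is EM to
#' convergence (relative log-likelihood change below `tol` or `max_iter`
#' iterations). Factors are ordered by variance explained, and each loading
#' column is sign-fixed so its largest-magnitude entry is positive.
#'
#' @param mat an [abundance_matrix()] (complete; run the preprocessing chain
#'   first) or a plain proteins x samples matrix.
#' @param k_max number of factors to fit (< min(dim)).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter maximum EM iterations (default 2000).
#' @param seed seed for the (small) random jitter added to the spectral
#'   initialisation; the fit is deterministic given the seed.
#' @return an object of class `factor_model`: list with `Z` (samples x K
#'   scores), `W` (proteins x K loadings), `noise_var` (per protein),
#'   `var_explained` (per-factor % of total variance, incremental), `K`,
#'   `converged`, `iterations`, `loglik`, `center` (per-protein means), and
#'   `meta` (sample metadata if available).
#' @export
fit_factor_model <- function(mat, k_max, tol = 1e-6, max_iter = 2000, seed = 1) {
  if (inherits(mat, "abundance_matrix")) {
    values <- mat$values
    meta <- mat$meta
    tplev <- mat$timepoint_levels
  } else {
    values <- as.matrix(mat)
    meta <- NULL
    tplev <- NULL
  }
  if (anyNA(values)) stop("fit_factor_model: matrix has missing values")
  n <- ncol(values); p <- nrow(values)
  if (k_max >= min(n, p)) stop("fit_factor_model: k_max must be < min(dim)")
  X <- t(values)                       # n x p
  center <- colMeans(X)
  X <- sweep(X, 2, center)

  # spectral initialisation + seeded jitter (deterministic given seed)
  sv <- svd(X, nu = 0, nv = k_max)
  set.seed(seed)
  W <- sv$v %*% diag(sv$d[seq_len(k_max)] / sqrt(n), k_max) +
    matrix(rnorm(p * k_max, sd = 1e-3), p, k_max)
  psi <- pmax(colMeans(X^2) - rowSums(W^2), 1e-4)

  ll_old <- -Inf; converged <- FALSE; iter <- 0
  sum_x2 <- colSums(X^2)
  for (iter in seq_len(max_iter)) {
    PiW <- W / psi                     # p x K
    M <- diag(k_max) + crossprod(W, PiW)
    Minv <- solve(M)
    A <- X %*% PiW                     # n x K
    EZ <- A %*% Minv                   # n x K posterior means
    # log-likelihood via the matrix inversion lemma
    ll <- -n / 2 * (p * log(2 * pi) + determinant(M)$modulus[1] + sum(log(psi)) +
                      (sum(sum_x2 / psi) - sum((A %*% Minv) * A)) / n)
    sum_Ezz <- n * Minv + crossprod(EZ)
    XtEZ <- crossprod(X, EZ)           # p x K
    W <- XtEZ %*% solve(sum_Ezz)
    psi <- pmax((sum_x2 - rowSums(XtEZ * W)) / n, 1e-8)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged)
    warning(sprintf("fit_factor_model: EM did not converge in %d iterations", iter))

  PiW <- W / psi
  Minv <- solve(diag(k_max) + crossprod(W, PiW))
  EZ <- X %*% PiW %*% Minv

  model <- structure(
    list(Z = EZ, W = W, noise_var = psi, K = k_max, center = center,
         converged = converged, iterations = iter, loglik = ll,
         meta = meta, timepoint_levels = tplev, temporal = FALSE),
    class = "factor_model")
  finalise_factor_model(model, X)
}

# internal: resolve rotational indeterminacy (varimax on the loadings, the
# same orthogonal rotation applied to the scores), order factors by variance
# explained, fix signs, compute incremental
# var_explained = 100 * (1 - SS_res(1..k)/SS_tot) increments.
finalise_factor_model <- function(model, Xc, rotate = TRUE) {
  Z <- model$Z; W <- model$W; K <- model$K
  if (rotate && K > 1) {
    R <- stats::varimax(W, normalize = FALSE)$rotmat
    W <- W %*% R
    Z <- Z %*% R
  }
  # greedy ordering by incremental variance explained: at each step take the
  # factor whose addition reduces SS_res most
  ss_tot <- sum(Xc^2)
  remaining <- seq_len(K); ord <- integer(0)
  recon <- matrix(0, nrow(Xc), ncol(Xc))
  cum <- numeric(K)
  prev <- 0
  for (step in seq_len(K)) {
    gains <- vapply(remaining, function(k) {
      r <- recon + tcrossprod(Z[, k], W[, k])
      100 * (1 - sum((Xc - r)^2) / ss_tot)
    }, 0)
    pick <- remaining[which.max(gains)]
    ord <- c(ord, pick)
    remaining <- setdiff(remaining, pick)
    recon <- recon + tcrossprod(Z[, pick], W[, pick])
    cum[step] <- max(gains)
  }
  Z <- Z[, ord, drop = FALSE]; W <- W[, ord, drop = FALSE]
  for (k in seq_len(K)) {
    s <- sign(W[which.max(abs(W[, k])), k])
    if (s < 0) { W[, k] <- -W[, k]; Z[, k] <- -Z[, k] }
  }
  ve <- pmax(diff(c(0, cum)), 0)   # tiny negative increments clamped
  dimnames(Z) <- list(rownames(Xc), paste0("factor", seq_len(K)))
  dimnames(W) <- list(colnames(Xc), paste0("factor", seq_len(K)))
  model$Z <- Z; model$W <- W; model$var_explained <- ve
  model$factor_order <- ord
  model
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("factor_model: %d factors over %d samples x %d proteins%s\n",
              x$K, nrow(x$Z), nrow(x$W),
              if (isTRUE(x$temporal)) " (temporal)" else ""))
  cat("  var_explained (%):", paste(sprintf("%.1f", x$var_explained), collapse = " "), "\n")
  if (!x$converged) cat(sprintf("  NOT converged (%d iterations)\n", x$iterations))
  invisible(x)
}

#' Retain factors above a variance-explained threshold
#'
#' Keeps factors explaining at least `threshold_pct` of total variance; at
#' least one factor (the largest) is always retained.
#'
#' @param model a `factor_model`.
#' @param threshold_pct retention threshold in percent (default 2).
#' @return the truncated `factor_model`.
#' @export
retain_factors <- function(model, threshold_pct = 2.0) {
  stopifnot(inherits(model, "factor_model"))
  keep <- which(model$var_explained >= threshold_pct)
  if (!length(keep)) keep <- 1L   # floor rule: never drop every factor
  model$Z <- model$Z[, keep, drop = FALSE]
  model$W <- model$W[, keep, drop = FALSE]
  model$var_explained <- model$var_explained[keep]
  if (!is.null(model$kernel_params))
    model$kernel_params <- model$kernel_params[keep, , drop = FALSE]
  if (!is.null(model$smoothness)) model$smoothness <- model$smoothness[keep]
  model$K <- length(keep)
  model
}

#' Factor scores of all patients at one timepoint
#'
#' @param model a `factor_model` fitted on a matrix that carried sample
#'   metadata.
#' @param timepoint timepoint label.
#' @return patients x factors matrix of scores (rownames = patient ids).
#' @export
factor_scores_at <- function(model, timepoint) {
  stopifnot(inherits(model, "factor_model"))
  if (is.null(model$meta))
    stop("factor_scores_at: model was fitted without sample metadata")
  avail <- unique(model$meta$timepoint)
  if (!timepoint %in% avail)
    stop(sprintf("factor_scores_at: timepoint '%s' absent; available: %s",
                 timepoint, paste(avail, collapse = ", ")))
  sel <- model$meta$timepoint == timepoint
  out <- model$Z[sel, , drop = FALSE]
  rownames(out) <- model$meta$patient_id[sel]
  out
}
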