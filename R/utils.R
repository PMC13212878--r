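#' Derive a substream seed from a run seed
#'
#' All stochastic stages derive their seed from one run seed through this
#' scheme, so a single integer reproduces the whole pipeline while stages
#' remain decoupled (inserting a draw in one stage does not shift another).
#'
#' @param seed integer run seed.
#' @param stream integer stream index (>= 0).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(stream))
  (as.integer(seed) %% 2147483646L + 1009L * as.integer(stream)) %% 2147483646L + 1L
}

#' Rank-based AUC of a score against a binary outcome
#'
#' Area under the ROC curve computed as the normalised Mann-Whitney U
#' statistic, `U / (n1 * n0)`, using midranks for ties. Equals the
#' probability that a random positive scores higher than a random negative
#' (ties counted 1/2).
#'
#' @param x numeric scores.
#' @param y binary outcome (0/1 or logical), 1 = positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(x, y) {
  y <- as.integer(as.logical(y))
  stopifnot(length(x) == length(y), all(y %in% c(0L, 1L)))
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) stop("auc_rank: both outcome classes must be present")
  r <- rank(x)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified fold assignment
#'
#' Assigns each observation to one of `k` folds, balancing the binary outcome
#' across folds. If the smaller class has fewer than `k` members the fold
#' count is reduced to that class size, with a warning.
#'
#' @param y binary outcome vector.
#' @param k requested number of folds.
#' @param seed integer seed for the shuffle.
#' @return integer vector of fold ids in `1..k'` (k' <= k), one per element of `y`.
#' @export
stratified_folds <- function(y, k, seed) {
  y <- as.integer(as.logical(y))
  n_min <- min(table(factor(y, levels = c(0L, 1L))))
  if (n_min < 2) stop("stratified_folds: need at least 2 per class")
  if (n_min < k) {
    warning(sprintf("fold count reduced from %d to %d (smallest class size)", k, n_min))
    k <- n_min
  }
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in c(0L, 1L)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# internal: ridge-penalised logistic regression by IRLS.
# Small fixed L2 penalty keeps tiny stratified folds estimable when classes
# separate perfectly; intercept unpenalised.
ridge_logistic <- function(X, y, lambda = 1e-2, max_iter = 100, tol = 1e-8) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(Xd, Xd * w) + pen
    beta_new <- solve(H, crossprod(Xd, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  list(intercept = beta[1], coef = drop(beta[-1]), lambda = lambda)
}

ridge_logistic_predict <- function(fit, X) {
  drop(plogis(fit$intercept + as.matrix(X) %*% fit$coef))
}
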