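#' Fit a temporally smooth latent factor model
#'
#' Longitudinal extension of [fit_factor_model()]: factor scores are
#' regularised toward smooth functions of a continuous time covariate via a
#' squared-exponential Gaussian-process prior per factor. Fitting alternates
#' (i) an EM-style score update given loadings and noise, (ii) GP-regression
#' smoothing of each factor's per-patient score trajectory, and (iii) a
#' penalised least-squares loading update, under a Gaussian likelihood.
#' GP hyperparameters (lengthscale and signal fraction) are selected per
#' factor by marginal-likelihood grid search.
#'
#' @param mat an [abundance_matrix()] with per-sample patient and timepoint
#'   metadata (time is taken as the integer timepoint index, weekly spacing).
#' @param k_max number of factors (default 15).
#' @param lengthscale optional fixed lengthscale (timepoint-index units). The
#'   default `NULL` selects per factor from `ls_grid`. A value `<= 1e-8`
#'   disables smoothing entirely, reproducing the non-temporal EM fit.
#' @param ls_grid lengthscale grid for marginal-likelihood selection.
#' @param sf_grid signal-fraction grid (share of a factor's score variance
#'   attributed to the smooth GP component vs observation noise).
#' @param n_iter alternating iterations (default 8).
#' @param ridge L2 penalty in the loading update.
#' @param seed seed passed to the inner EM initialisation.
#' @return a `factor_model` with additional fields `kernel_params`
#'   (per-factor data.frame: `lengthscale`, `signal_fraction`) and
#'   `smoothness` (per-factor share of raw score variance captured by the
#'   smooth component), `temporal = TRUE`.
#' @export
fit_temporal_model <- function(mat, k_max = 15, lengthscale = NULL,
                               ls_grid = c(0.75, 1.5, 3, 6),
                               sf_grid = c(0.1, 0.3, 0.5, 0.7, 0.9, 0.99, 0.999),
                               n_iter = 8, ridge = 1e-3, seed = 1) {
  stopifnot(inherits(mat, "abundance_matrix"))
  if (length(unique(mat$meta$timepoint)) < 2) {
    warning("fit_temporal_model: single timepoint; falling back to fit_factor_model")
    return(fit_factor_model(mat, k_max, seed = seed))
  }
  base <- fit_factor_model(mat, k_max, seed = seed)
  if (!is.null(lengthscale) && lengthscale <= 1e-8) {
    # no-smoothing limit: identical to the non-temporal EM fit
    base$temporal <- TRUE
    base$kernel_params <- data.frame(lengthscale = rep(0, base$K),
                                     signal_fraction = rep(0, base$K))
    base$smoothness <- rep(1, base$K)
    return(base)
  }
  if (!is.null(lengthscale)) ls_grid <- lengthscale

  values <- mat$values
  X <- sweep(t(values), 2, base$center)     # n x p, centered
  n <- nrow(X); p <- ncol(X)
  time <- timepoint_index(mat)
  patient <- mat$meta$patient_id
  pat_split <- split(seq_len(n), patient)

  W <- base$W; psi <- base$noise_var
  sum_x2 <- colSums(X^2)
  kernel <- data.frame(lengthscale = rep(NA_real_, k_max),
                       signal_fraction = rep(NA_real_, k_max))
  smoothness <- rep(NA_real_, k_max)
  EZ <- base$Z; Zs <- EZ

  for (it in seq_len(n_iter)) {
    PiW <- W / psi
    Minv <- solve(diag(k_max) + crossprod(W, PiW))
    EZ <- X %*% PiW %*% Minv
    for (k in seq_len(k_max)) {
      sm <- gp_smooth_factor(EZ[, k], time, pat_split, ls_grid, sf_grid)
      Zs[, k] <- sm$smooth
      kernel$lengthscale[k] <- sm$lengthscale
      kernel$signal_fraction[k] <- sm$signal_fraction
    }
    ZtZ <- crossprod(Zs) + diag(ridge, k_max)
    XtZ <- crossprod(X, Zs)
    W <- XtZ %*% solve(ZtZ)
    psi <- pmax((sum_x2 - rowSums(XtZ * W)) / n, 1e-8)
  }
  v_raw <- apply(EZ, 2, var)
  smoothness <- pmin(apply(Zs, 2, var) / pmax(v_raw, 1e-12), 1)

  model <- structure(
    list(Z = Zs, W = W, noise_var = psi, K = k_max, center = base$center,
         converged = TRUE, iterations = n_iter, loglik = NA_real_,
         meta = mat$meta, timepoint_levels = mat$timepoint_levels,
         temporal = TRUE),
    class = "factor_model")
  # order factors, fix signs; reorder kernel/smoothness the same way
  model <- finalise_factor_model(model, X)
  ord <- model$factor_order
  model$kernel_params <- kernel[ord, , drop = FALSE]
  rownames(model$kernel_params) <- colnames(model$Z)
  model$smoothness <- setNames(smoothness[ord], colnames(model$Z))
  model
}

# internal: GP-smooth one factor's scores along each patient's time course,
# with squared-exponential kernel hyperparameters chosen by the summed
# per-patient log marginal likelihood over a grid.
gp_smooth_factor <- function(z, time, pat_split, ls_grid, sf_grid) {
  v <- var(z)
  if (!is.finite(v) || v < 1e-12)
    return(list(smooth = z, lengthscale = ls_grid[1], signal_fraction = 0))
  best <- NULL; best_ll <- -Inf
  for (ls in ls_grid) for (sf in sf_grid) {
    ll <- 0
    for (idx in pat_split) {
      t_i <- time[idx]; z_i <- z[idx]; m <- length(idx)
      Km <- v * sf * exp(-0.5 * (outer(t_i, t_i, "-") / ls)^2) +
        diag(v * (1 - sf) + 1e-9, m)
      ch <- chol(Km)
      a <- backsolve(ch, forwardsolve(t(ch), z_i))
      ll <- ll - 0.5 * sum(z_i * a) - sum(log(diag(ch))) - 0.5 * m * log(2 * pi)
    }
    if (ll > best_ll) { best_ll <- ll; best <- c(ls, sf) }
  }
  ls <- best[1]; sf <- best[2]
  smooth <- z
  for (idx in pat_split) {
    t_i <- time[idx]; z_i <- z[idx]; m <- length(idx)
    Ks <- v * sf * exp(-0.5 * (outer(t_i, t_i, "-") / ls)^2)
    smooth[idx] <- drop(Ks %*% solve(Ks + diag(v * (1 - sf) + 1e-9, m), z_i))
  }
  list(smooth = smooth, lengthscale = ls, signal_fraction = sf)
}
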