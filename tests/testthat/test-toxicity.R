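test_that("patient clustering separates blobs and keeps duplicates together", {
  set.seed(1)
  Z <- rbind(matrix(rnorm(10 * 3, 0), 10, 3), matrix(rnorm(10 * 3, 6), 10, 3))
  rownames(Z) <- sprintf("P%02d", 1:20)
  cl <- cluster_patients(Z)
  expect_equal(length(unique(cl$clusters[1:10])), 1)
  expect_equal(length(unique(cl$clusters[11:20])), 1)
  expect_false(cl$clusters[1] == cl$clusters[11])

  Zd <- rbind(Z, P99 = Z[1, ])
  cld <- cluster_patients(Zd)
  expect_equal(unname(cld$clusters["P99"]), unname(cld$clusters["P01"]))

  expect_error(cluster_patients(Z[1:3, ]), ">= 4")
})

test_that("a planted d=2 toxicity factor drives cluster recovery", {
  agree <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 26
    y <- rep(c(0, 1), c(9, 17))
    Z <- cbind(rnorm(n) + 2 * y, matrix(rnorm(n * 2), n, 2))
    rownames(Z) <- sprintf("P%02d", 1:n)
    cl <- cluster_patients(Z)
    max(mean((cl$clusters == 1) == (y == 1)), mean((cl$clusters == 2) == (y == 1)))
  }, 0)
  expect_gte(median(agree), 0.8)
})

test_that("Fisher association equals hypergeometric enumeration", {
  # [[5,0],[0,5]] -> 2 / choose(10,5) = 2/252
  cl <- rep(c("a", "b"), each = 5)
  y <- rep(c(1, 0), each = 5)
  fa <- fisher_association(cl, y)
  expect_equal(fa$p, 2 / 252, tolerance = 1e-12)

  # perfect independence -> p = 1
  fa2 <- fisher_association(rep(c("a", "b"), each = 4), rep(c(0, 1), 4))
  expect_equal(fa2$p, 1)

  # oracle equivalence on random tables with n <= 30
  set.seed(2)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    cl_i <- sample(c("a", "b"), n, replace = TRUE)
    y_i <- sample(0:1, n, replace = TRUE)
    if (length(unique(cl_i)) < 2) cl_i[1:2] <- c("a", "b")
    if (length(unique(y_i)) < 2) next
    fa_i <- fisher_association(cl_i, y_i)
    expect_equal(fa_i$p, fisher_enum(fa_i$table), tolerance = 1e-9)
  }

  # transposition / label-swap invariance
  tab <- matrix(c(6, 2, 3, 8), 2)
  expect_equal(fisher_enum(tab), fisher_enum(t(tab)), tolerance = 1e-12)
  cl3 <- rep(c("a", "b"), c(8, 11)); y3 <- rbinom(19, 1, 0.5)
  y3[1:2] <- c(0, 1)
  expect_equal(fisher_association(cl3, y3)$p,
               fisher_association(ifelse(cl3 == "a", "b", "a"), y3)$p)

  expect_warning(fa4 <- fisher_association(rep(c("a", "b"), 4), rep(1, 8)),
                 "degenerate")
  expect_equal(fa4$p, 1)
})

test_that("factor-cluster differences use Welch t with a Bonferroni cap", {
  set.seed(3)
  Z <- matrix(rnorm(20 * 9), 20, 9, dimnames = list(NULL, paste0("factor", 1:9)))
  cl <- rep(c(1, 2), each = 10)
  Z[, 4] <- Z[, 4] + 3 * (cl == 2)
  fd <- factor_cluster_difference(Z, cl)
  expect_equal(fd$p_bonf, pmin(1, fd$p * 9))
  expect_equal(fd$factor[which.min(fd$p_bonf)], "factor4")
  ref <- t.test(Z[cl == 1, 1], Z[cl == 2, 1])
  expect_equal(fd$p[1], ref$p.value)
  # raw p 0.003 over 9 factors -> adjusted 0.027
  expect_equal(min(1, 0.003 * 9), 0.027)
  expect_error(factor_cluster_difference(Z, rep(c(1, 2), c(1, 19))), ">= 2")
})

test_that("the planted separating factor wins the cluster test almost always", {
  wins <- vapply(1:50, function(s) {
    set.seed(s)
    Z <- matrix(rnorm(24 * 5), 24, 5, dimnames = list(NULL, paste0("factor", 1:5)))
    cl <- rep(c(1, 2), each = 12)
    Z[, 2] <- Z[, 2] + 2.5 * (cl == 2)
    fd <- factor_cluster_difference(Z, cl)
    fd$factor[which.min(fd$p_bonf)] == "factor2"
  }, TRUE)
  expect_gte(mean(wins), 0.95)
})

test_that("top-weight selection takes ceil(fraction * n) with deterministic ties", {
  set.seed(4)
  W <- matrix(rnorm(600 * 2), 600, 2,
              dimnames = list(sprintf("G%03d", 1:600), c("factor1", "factor2")))
  top <- top_weight_proteins(W, 1, 0.05)
  expect_equal(nrow(top), 30)
  expect_equal(top$loading, unname(W[top$protein, 1]))
  expect_true(all(abs(top$loading) >= max(abs(W[setdiff(rownames(W), top$protein), 1])) - 1e-12))

  We <- matrix(1, 40, 1, dimnames = list(sprintf("G%02d", 1:40), "factor1"))
  expect_warning(te <- top_weight_proteins(We, 1, 0.05), "ties")
  expect_equal(te$protein, sort(rownames(We))[1:2])
  expect_error(top_weight_proteins(W, 1, 0), "fraction")
  expect_error(top_weight_proteins(W, 1, 1.2), "fraction")
})

test_that("permutation loading p-values behave as rank statistics", {
  set.seed(5)
  w <- rnorm(199)
  w[200] <- 10               # clear maximum
  W <- matrix(w, 200, 1, dimnames = list(sprintf("G%03d", 1:200), "factor1"))
  pp <- permutation_loading_test(W, 1, B = 1000, seed = 3)
  expect_equal(pp$perm_p[200], 1 / 1001)

  # a loading at the median of |w| sits near p = 0.5
  med_i <- which.min(abs(abs(w) - median(abs(w))))
  expect_lt(abs(pp$perm_p[med_i] - 0.5), 0.05)

  # deterministic given seed
  pp2 <- permutation_loading_test(W, 1, B = 1000, seed = 3)
  expect_identical(pp$perm_p, pp2$perm_p)
  expect_error(permutation_loading_test(W, 1, B = 50), "B must be")
})

test_that("permutation p-values are uniform under an exchangeable null", {
  ks_p <- vapply(1:50, function(s) {
    set.seed(s)
    W <- matrix(rnorm(150), 150, 1, dimnames = list(sprintf("G%03d", 1:150), "f"))
    pp <- permutation_loading_test(W, 1, B = 400, seed = s + 1000)
    # compare against the discrete uniform the add-one rule induces
    suppressWarnings(stats::ks.test(pp$perm_p, "punif", 1 / 401, 1)$p.value)
  }, 0)
  expect_gt(mean(ks_p > 0.01), 0.9)
})

test_that("fold-change validation flags strictly-more-than-two-fold shifts", {
  n <- 10
  y <- rep(c(0, 1), each = 5)
  base <- matrix(0, 3, n)
  base[2, y == 1] <- 1         # exactly two-fold: boundary, not flagged
  base[3, y == 1] <- 1.5       # flagged up
  m <- make_matrix(base, sprintf("P%02d", 1:n), "t0", toxicity = y)
  fc <- fold_change_validation(m, "t0")
  expect_equal(fc$flag, c("none", "none", "up"))
  expect_equal(fc$log2_fc[1], 0, tolerance = 1e-6)

  m_bad <- make_matrix(base, sprintf("P%02d", 1:n), "t0", toxicity = rep(1, n))
  expect_error(fold_change_validation(m_bad, "t0"), "non-empty")
})

test_that("univariable screening produces d, U-test p, and AUC as specified", {
  r <- univariable_screen(c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 1.0)
  expect_equal(r$d_class, "large")

  r2 <- univariable_screen(rep(c(1, 2, 3), 2), rep(c(0, 1), each = 3))
  expect_equal(r2$cohens_d, 0)
  expect_equal(r2$auc, 0.5)

  # means 0 vs 1 at pooled SD 1 -> d = 1, "large separation"
  set.seed(6)
  x0 <- rnorm(200); x0 <- (x0 - mean(x0)) / sd(x0)
  x1 <- rnorm(200); x1 <- (x1 - mean(x1)) / sd(x1) + 1
  r3 <- univariable_screen(c(x0, x1), rep(c(0, 1), each = 200))
  expect_equal(r3$cohens_d, 1, tolerance = 1e-9)
  expect_equal(r3$d_class, "large")

  expect_error(univariable_screen(1:4, rep(1, 4)), "one-class")
})

test_that("AUC equals U/(n1 n0) and the pairwise-win probability", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(6:12, 1)
    y <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    x <- sample(1:6, n, replace = TRUE)  # ties included
    expect_equal(auc_rank(x, y), auc_brute(x, y), tolerance = 1e-12)
    w <- wilcox.test(x[y == 1], x[y == 0], exact = FALSE)
    expect_equal(auc_rank(x, y), unname(w$statistic) / (sum(y) * sum(1 - y)),
                 tolerance = 1e-12)
  }
})

test_that("bootstrap AUC CI is percentile-based and honours B", {
  x <- c(1, 2, 3, 10, 11, 12)
  y <- rep(c(0, 1), each = 3)
  ci <- bootstrap_auc_ci(x, y, B = 200, seed = 1)
  expect_equal(ci$ci, c(1, 1))
  expect_equal(ci$B, 200)
  ci_b <- bootstrap_auc_ci(x, y, B = 200, seed = 1)
  expect_identical(ci, ci_b)
})

test_that("bootstrap CI covers 0.5 under the null", {
  cover <- vapply(1:60, function(s) {
    set.seed(s)
    x <- rnorm(24); y <- rep(c(0, 1), each = 12)
    ci <- bootstrap_auc_ci(x, y, B = 300, seed = s + 500)$ci
    ci[1] <= 0.5 && 0.5 <= ci[2]
  }, TRUE)
  expect_gte(mean(cover), 0.9)
})

test_that("logistic OR matches the cross-product ratio and reparameterises exactly", {
  # binary predictor with counts [[6,2],[2,6]] -> OR 9
  x <- rep(c(0, 1), each = 8)
  y <- c(rep(0, 6), rep(1, 2), rep(0, 2), rep(1, 6))
  r <- logistic_or(x, y)
  expect_equal(r$or, 9, tolerance = 1e-6)
  r2 <- logistic_or(2 * x, y)
  expect_equal(r2$slope, r$slope / 2, tolerance = 1e-6)

  # perfect separation is flagged, not silently diverged
  rs <- logistic_or(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3))
  expect_true(rs$separable)
  expect_true(is.na(rs$or))
})

test_that("Wald CI covers the null OR under independence", {
  cover <- vapply(1:100, function(s) {
    set.seed(s)
    x <- rnorm(40); y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    r <- logistic_or(x, y)
    !r$separable && r$or_lo <= 1 && 1 <= r$or_hi
  }, TRUE)
  expect_gte(mean(cover), 0.9)
})

test_that("biomarker records integrate loading, permutation, fold change, OR, AUC", {
  cc <- cohort_config(n_patients = 14, n_proteins = 60, n_kinetic = 0,
                      toxicity_effect = 2, frac_toxic = 0.5, seed = 8)
  sim <- simulate_cohort(cc)
  pre <- preprocess_pipeline(sim$abundance)
  fm <- retain_factors(fit_factor_model(pre, 4, seed = 1), 2)
  bm <- biomarker_records(pre, fm, factor = 1, timepoint = "t0",
                          B = 200, seed = 2)
  expect_equal(nrow(bm), 3)          # ceil(0.05 * 60)
  expect_true(all(bm$perm_p > 0 & bm$perm_p <= 1))
  expect_true(all(c("loading", "perm_p", "log2_fc", "or", "auc") %in% names(bm)))
})
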