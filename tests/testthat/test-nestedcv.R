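test_that("stratified folds balance classes and cap at the smaller class", {
  y <- rep(c(0, 1), c(20, 10))
  f <- stratified_folds(y, 5, seed = 1)
  expect_equal(max(f), 5)
  for (k in 1:5) expect_equal(sum(y[f == k]), 2)   # two positives per fold
  expect_warning(f2 <- stratified_folds(rep(c(0, 1), c(20, 3)), 10, seed = 1),
                 "reduced")
  expect_equal(max(f2), 3)
  expect_error(stratified_folds(rep(c(0, 1), c(29, 1)), 5, "at least 2"))
})

test_that("a planted strong feature dominates nested CV", {
  set.seed(1)
  n <- 30
  y <- rep(c(0, 1), each = 15)
  X <- cbind(planted = rnorm(n) + 2 * y, matrix(rnorm(n * 5), n, 5))
  colnames(X)[-1] <- paste0("noise", 1:5)
  res <- nested_cv(X, y, outer_folds = 5, inner_folds = 5, inner_repeats = 10,
                   seed = 2)
  expect_gte(res$outer_auc, 0.85)
  expect_gte(res$selection_freq["planted"], 0.9)
  expect_equal(unname(res$stability_band["planted"]), "highly_reproducible")
})

test_that("duplicated features share selection frequency symmetrically", {
  set.seed(2)
  n <- 30
  y <- rep(c(0, 1), each = 15)
  x <- rnorm(n) + 1.5 * y
  X <- cbind(a = x, b = x, c = rnorm(n))
  res <- nested_cv(X, y, outer_folds = 5, inner_folds = 3, inner_repeats = 10,
                   top_k = 2, seed = 3)
  expect_lt(abs(res$selection_freq["a"] - res$selection_freq["b"]), 0.1)
})

test_that("outer-test labels never leak into selection or training", {
  set.seed(3)
  n <- 24
  y <- rep(c(0, 1), each = 12)
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y_corrupt <- 1 - y
  r1 <- nested_cv(X, y, outer_folds = 4, inner_folds = 3, inner_repeats = 5,
                  seed = 4)
  r2 <- nested_cv(X, y, outer_folds = 4, inner_folds = 3, inner_repeats = 5,
                  seed = 4, outcome_eval = y_corrupt)
  expect_identical(r1$chosen_features, r2$chosen_features)
  expect_identical(r1$selection_freq, r2$selection_freq)
  expect_false(isTRUE(all.equal(r1$outer_auc, r2$outer_auc)))
  expect_equal(r1$outer_auc + r2$outer_auc, 1, tolerance = 1e-9)
})

test_that("nested CV is deterministic given the seed", {
  set.seed(5)
  X <- matrix(rnorm(26 * 4), 26, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c(0, 1), c(9, 17))
  r1 <- nested_cv(X, y, outer_folds = 4, inner_folds = 3, inner_repeats = 5, seed = 11)
  r2 <- nested_cv(X, y, outer_folds = 4, inner_folds = 3, inner_repeats = 5, seed = 11)
  expect_identical(r1$fold_ids, r2$fold_ids)
  expect_identical(r1$outer_auc, r2$outer_auc)
})

test_that("composite ranking rewards dominance and is affine-invariant", {
  auc <- c(a = 0.9, b = 0.6, c = 0.7)
  p <- c(a = 1e-4, b = 0.2, c = 0.05)
  st <- c(a = 0.95, b = 0.3, c = 0.6)
  r <- composite_rank(auc, p, st)
  expect_equal(r$feature[1], "a")

  # affine rescaling of one raw component leaves scores unchanged
  r2 <- composite_rank(auc * 10 + 3, p, st)
  expect_equal(r$score, r2$score, tolerance = 1e-12)

  expect_warning(r3 <- composite_rank(c(a = 0.5, b = 0.5), c(a = 0.1, b = 0.1),
                                      c(a = 0.5, b = 0.5)), "tie")
  expect_equal(r3$feature, c("a", "b"))
  expect_equal(r3$score[1], r3$score[2])
  expect_error(composite_rank(1:3, 1:2, 1:3), "equal length")
})

test_that("bootstrap refit AUC hits the separable ceiling and records B", {
  x <- c(rnorm(10), rnorm(10) + 8)
  y <- rep(c(0, 1), each = 10)
  X <- cbind(f = x)
  res <- bootstrap_refit_auc(X, y, B = 100, seed = 1)
  expect_equal(res$ci[2], 1)
  expect_equal(res$B, 100)
  expect_true(res$optimism_prone)
})

test_that("bootstrap refit CI brackets the apparent AUC it resamples", {
  # the refit bootstrap is an in-sample (optimism-prone) statistic: its CI
  # tracks the full-data apparent AUC, not the generalisation AUC
  cover <- vapply(1:40, function(s) {
    set.seed(s)
    X <- matrix(rnorm(24 * 2), 24, 2, dimnames = list(NULL, c("a", "b")))
    y <- rep(c(0, 1), each = 12)
    res <- bootstrap_refit_auc(X, y, B = 100, seed = s + 10)
    res$ci[1] <= res$auc && res$auc <= res$ci[2]
  }, TRUE)
  expect_gte(mean(cover), 0.85)
})

test_that("nested CV is less optimistic than bootstrap refitting on average", {
  diffs <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 26
    y <- rep(c(0, 1), c(12, 14))
    X <- cbind(f1 = rnorm(n) + 0.8 * y, f2 = rnorm(n), f3 = rnorm(n))
    ncv <- nested_cv(X, y, outer_folds = 4, inner_folds = 3, inner_repeats = 5,
                     top_k = 2, seed = s)
    boot <- bootstrap_refit_auc(X, y, B = 60, seed = s)
    boot$auc - ncv$outer_auc
  }, 0)
  expect_gt(mean(diffs), 0)
})
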