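test_that("paired t contrast handles identity, hand-worked, and degenerate cases", {
  # identical columns -> fc 0, p 1
  v <- matrix(rnorm(12), 3, 4)
  m <- make_matrix(cbind(v[, 1], v[, 1], v[, 2], v[, 2], v[, 3], v[, 3],
                         v[, 4], v[, 4]),
                   c("A", "B", "C", "D"), c("t0", "t1"))
  res <- paired_t_contrast(m, "t0", "t1")
  expect_equal(res$log2_fc, rep(0, 3))
  expect_equal(res$p, rep(1, 3))

  # differences (1, 2, 3): t = 2/(1/sqrt(3)) = 3.4641; p from the closed-form
  # df-2 t CDF, F(t) = 1/2 + t / (2*sqrt(2)*sqrt(1 + t^2/2))
  base <- rnorm(3)
  vals <- matrix(NA_real_, 1, 6)   # columns interleave t0/t1 per patient
  vals[1, c(1, 3, 5)] <- base
  vals[1, c(2, 4, 6)] <- base + c(1, 2, 3)
  m2 <- make_matrix(vals, c("A", "B", "C"), c("t0", "t1"))
  r2 <- paired_t_contrast(m2, "t0", "t1")
  tt <- 2 / (1 / sqrt(3))
  expect_equal(r2$t_stat, tt, tolerance = 1e-4)
  p_oracle <- 2 * (1 - (0.5 + tt / (2 * sqrt(2) * sqrt(1 + tt^2 / 2))))
  expect_equal(r2$p, p_oracle, tolerance = 1e-6)
  expect_equal(r2$p, 0.0742, tolerance = 1e-3)

  # zero-variance nonzero differences -> smallest representable p
  v3 <- matrix(c(0, 1, 0, 1, 0, 1), 1, 6)
  m3 <- make_matrix(v3, c("A", "B", "C"), c("t0", "t1"))
  expect_equal(paired_t_contrast(m3, "t0", "t1")$p, .Machine$double.xmin)

  expect_error(paired_t_contrast(m2, "t0", "t9"), "unknown timepoint")
})

test_that("patients lacking either timepoint are excluded from the whole contrast", {
  cc <- cohort_config(n_patients = 6, n_proteins = 10, n_kinetic = 0, seed = 2)
  sim <- simulate_cohort(cc)
  dropped <- subset_samples(sim$abundance,
                            setdiff(sim$meta$sample_id, "P01_t1"))
  res <- paired_t_contrast(dropped, "t0", "t1")
  expect_true(all(res$n_pairs == 5))
})

test_that("paired t equals one-sample t on the differences", {
  set.seed(3)
  x <- rnorm(8); y <- rnorm(8, 0.4)
  vals <- matrix(NA_real_, 1, 16)
  vals[1, seq(1, 15, 2)] <- x
  vals[1, seq(2, 16, 2)] <- y
  m <- make_matrix(vals, sprintf("P%d", 1:8), c("t0", "t1"))
  res <- paired_t_contrast(m, "t0", "t1")
  ref <- t.test(y - x)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  expect_equal(res$t_stat, unname(ref$statistic), tolerance = 1e-12)
})

test_that("type-I error of the paired contrast sits at alpha", {
  set.seed(11)
  n <- 10; p <- 2000
  vals <- matrix(rnorm(p * 2 * n, sd = 0.45), p, 2 * n)
  m <- make_matrix(vals, sprintf("P%02d", 1:n), c("t0", "t1"))
  res <- paired_t_contrast(m, "t0", "t1")
  rate <- mean(res$p < 0.05)
  se <- sqrt(0.05 * 0.95 / p)
  expect_lt(abs(rate - 0.05), 2 * se + 1e-12)
})

test_that("planted one-log2-unit shift is detected with at least 80% power at n=11", {
  set.seed(21)
  n <- 11; p <- 200
  t0 <- matrix(rnorm(p * n, 20, 0.45), p, n)
  t1 <- t0 * 0 + rnorm(p * n, 21, 0.45)   # independent draws, shift delta = 1
  vals <- matrix(NA_real_, p, 2 * n)
  vals[, seq(1, 2 * n, 2)] <- t0
  vals[, seq(2, 2 * n, 2)] <- t1
  m <- make_matrix(vals, sprintf("P%02d", 1:n), c("t0", "t1"))
  res <- paired_t_contrast(m, "t0", "t1")
  expect_gte(mean(res$p < 0.05), 0.8)
})

test_that("BH adjustment matches the step-up formula and controls FDR", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # hand-worked: q_(i) = min_{j>=i} p_(j) m / j
  p <- c(0.001, 0.02, 0.03, 0.5)
  expect_equal(bh_adjust(p), c(0.004, 0.04, 0.04, 0.5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1, 0.5)), "\\[0, 1\\]")

  # realised false-discovery proportion under the global null
  set.seed(5)
  fdp <- replicate(50, {
    q <- bh_adjust(runif(1000))
    mean(q < 0.05)
  })
  expect_lte(mean(fdp), 0.05)
})

test_that("RM-ANOVA matches its conventions, the paired-t identity, and aov", {
  # all timepoints identical per patient -> F = 0, p = 1
  v <- matrix(rep(rnorm(4), each = 3), 1, 12, byrow = FALSE)
  vals <- matrix(NA_real_, 1, 12)
  for (i in 1:4) vals[1, (i - 1) * 3 + 1:3] <- rnorm(1)
  m <- make_matrix(vals, sprintf("P%d", 1:4), paste0("t", 0:2))
  r <- rm_anova(m)
  expect_equal(r$f_stat, 0)
  expect_equal(r$p, 1)

  # two timepoints: F equals the squared paired-t statistic
  set.seed(6)
  vals2 <- matrix(rnorm(2 * 12), 2, 12)
  m2 <- make_matrix(vals2, sprintf("P%d", 1:6), c("t0", "t1"))
  ra <- rm_anova(m2)
  rt <- paired_t_contrast(m2, "t0", "t1")
  expect_equal(ra$f_stat, rt$t_stat^2, tolerance = 1e-10)
  expect_equal(ra$p, rt$p, tolerance = 1e-10)

  # independent oracle: stats::aov with a patient error stratum
  set.seed(7)
  vals3 <- matrix(rnorm(3 * 20), 3, 20)
  m3 <- make_matrix(vals3, sprintf("P%d", 1:5), paste0("t", 0:3))
  r3 <- rm_anova(m3)
  for (j in 1:3) {
    df <- data.frame(y = vals3[j, ],
                     patient = factor(m3$meta$patient_id),
                     tp = factor(m3$meta$timepoint))
    fit <- summary(aov(y ~ tp + Error(patient), data = df))
    ref <- fit[["Error: Within"]][[1]]
    expect_equal(r3$f_stat[j], ref[["F value"]][1], tolerance = 1e-8)
    expect_equal(r3$p[j], ref[["Pr(>F)"]][1], tolerance = 1e-8)
  }
})

test_that("RM-ANOVA detects planted time trends", {
  set.seed(8)
  n <- 12; Tn <- 4; p <- 60
  trend <- outer(rep(1, p), seq(0, 1, length.out = Tn))
  vals <- matrix(NA_real_, p, n * Tn)
  for (i in 1:n) vals[, (i - 1) * Tn + 1:Tn] <- trend + matrix(rnorm(p * Tn, sd = 0.45), p, Tn)
  m <- make_matrix(vals, sprintf("P%02d", 1:n), paste0("t", 0:3))
  r <- rm_anova(m)
  expect_gte(mean(r$p < 0.05), 0.95)
})

test_that("DAP set algebra matches brute-force region enumeration", {
  mk <- function(sig, universe) {
    q <- rep(0.5, length(universe)); q[match(sig, universe)] <- 0.01
    structure(data.frame(protein = universe, log2_fc = 0, t_stat = 0,
                         p = q, q = q, n_pairs = 5,
                         direction = "up", stringsAsFactors = FALSE),
              class = c("dea_result", "data.frame"))
  }
  universe <- sprintf("G%02d", 1:30)
  # disjoint sets -> empty intersection
  r <- dap_sets(list(a = mk(universe[1:5], universe),
                     b = mk(universe[6:10], universe)))
  expect_false("a&b" %in% r$regions$region)
  expect_equal(sum(r$regions$count), 10)

  # three identical sets of 10 -> all common
  r2 <- dap_sets(list(a = mk(universe[1:10], universe),
                      b = mk(universe[1:10], universe),
                      c = mk(universe[1:10], universe)))
  expect_equal(r2$regions$count[r2$regions$region == "a&b&c"], 10)
  expect_equal(nrow(r2$regions), 1)

  # random assignment vs power-set oracle
  set.seed(9)
  sigs <- lapply(1:3, function(i) sample(universe, sample(5:15, 1)))
  r3 <- dap_sets(setNames(lapply(sigs, mk, universe = universe), c("x", "y", "z")))
  for (g in universe) {
    pat <- vapply(sigs, function(s) g %in% s, TRUE)
    if (!any(pat)) next
    lab <- paste(c("x", "y", "z")[pat], collapse = "&")
    expect_true(g %in% r3$members[[lab]])
  }
  expect_equal(sum(r3$regions$count), length(unique(unlist(sigs))))

  expect_error(dap_sets(list(a = mk(universe[1], universe),
                             b = mk("OTHER", c("OTHER", universe[-1])))),
               "universe")
})
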