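test_that("permutation test degenerate and invariance behaviour", {
  g <- rep(c("control", "patient"), each = 10)
  v <- c(rnorm(10), rnorm(10))
  # identical values in both groups
  res <- permutation_test(c(1:10, 1:10), g, n_perm = 500, seed = 1)
  expect_equal(res$p, 1)
  # constant input
  expect_equal(permutation_test(rep(2, 20), g, n_perm = 100)$p, 1)
  # relabeling the groups flips the sign, keeps p
  r1 <- permutation_test(v, g, n_perm = 999, seed = 7)
  r2 <- permutation_test(v, rev(g), n_perm = 999, seed = 7)
  expect_equal(r1$p, r2$p)
  # shifting all values changes nothing
  r3 <- permutation_test(v + 100, g, n_perm = 999, seed = 7)
  expect_equal(r1$p, r3$p)
  expect_equal(r1$difference, r3$difference)
  expect_error(permutation_test(v, rep("a", 20)), "two groups")
  expect_error(permutation_test(v[1:3], c("a", "a", "b")), "at least 2")
})

test_that("permutation p is never zero and honors add-one smoothing", {
  v <- c(rep(0, 10), rep(100, 10))
  g <- rep(c("a", "b"), each = 10)
  res <- permutation_test(v, g, n_perm = 1000, seed = 3)
  expect_gte(res$p, 1 / 1001)
})

test_that("the permutation test is well powered at a d = 1.33 effect", {
  set.seed(17)
  ps <- vapply(1:40, function(i) {
    v <- c(rnorm(20, 0, 1), rnorm(20, 1.33, 1))
    permutation_test(v, rep(c("a", "b"), each = 20), n_perm = 2000)$p
  }, numeric(1))
  expect_gt(mean(ps < 0.001), 0.5)
})

test_that("BH adjustment matches the hand computation", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  # order invariance
  p <- c(0.04, 0.001, 0.3, 0.02)
  o <- order(p)
  expect_equal(bh_fdr(p)[o], bh_fdr(p[o]))
  expect_error(bh_fdr(c(0.5, 0)), "in \\(0, 1\\]")
})

test_that("partial correlation reduces to Pearson without covariates", {
  set.seed(23)
  x <- rnorm(30); y <- rnorm(30)
  pc <- partial_correlation(x, y)
  expect_equal(pc$r, cor(x, y), tolerance = 1e-12)
  expect_equal(pc$p, cor.test(x, y)$p.value, tolerance = 1e-9)
  # y = x gives r = 1 even with unrelated covariates
  z <- matrix(rnorm(60), 30)
  expect_equal(partial_correlation(x, x, z)$r, 1, tolerance = 1e-9)
})

test_that("partial correlation recovers the generating partial structure", {
  set.seed(24)
  n <- 10000
  z <- rnorm(n)
  # given z, residual correlation is 0.5 by construction
  e <- MASS::mvrnorm(n, c(0, 0), matrix(c(1, 0.5, 0.5, 1), 2))
  x <- 2 * z + e[, 1]
  y <- -1 * z + e[, 2]
  pc <- partial_correlation(x, y, cbind(z))
  expect_lt(abs(pc$r - 0.5), 0.03)
  # affine rescaling of x, y, covariates changes nothing
  pc2 <- partial_correlation(10 * x + 3, -2 * y + 1, cbind(5 * z - 7))
  expect_equal(abs(pc2$r), abs(pc$r), tolerance = 1e-9)
})

test_that("collinear covariates are reported by name", {
  set.seed(25)
  x <- rnorm(20); y <- rnorm(20)
  cov <- cbind(a = 1:20, b = 2 * (1:20))
  expect_error(partial_correlation(x, y, cov), "collinear.*b")
})

test_that("group comparison table has the right shape and FDR family", {
  set.seed(126)
  metrics <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:20),
    group = factor(rep(c("control", "patient"), each = 10)),
    gamma = rnorm(20, 8, 1), Q = rnorm(20, 0.7, 0.03),
    lambda = c(rnorm(10, 1.41, 0.08), rnorm(10, 1.52, 0.16)),
    E = c(rnorm(10, 0.63e-3, 0.03e-3), rnorm(10, 0.59e-3, 0.03e-3)),
    sigma = rnorm(20, 5.5, 1))
  cmp <- compare_groups(metrics, n_perm = 2000, seed = 2)
  expect_equal(nrow(cmp), 5)
  expect_equal(cmp$measure, c("gamma", "Q", "lambda", "E", "sigma"))
  expect_equal(cmp$q, bh_fdr(cmp$p))
  expect_true(all(cmp$p > 0 & cmp$p <= 1))
  # E difference is detected, direction control > patient
  expect_lt(cmp$q[cmp$measure == "E"], 0.05)
  expect_gt(cmp$difference[cmp$measure == "E"], 0)
  g <- glance(cmp)
  expect_equal(g$n_control, 10)
  expect_equal(g$n_measures, 5)
})

test_that("analyze_cohort joins records and errors on mismatched ids", {
  set.seed(27)
  ch <- generate_cohort(small_config(), seed = 3)
  m <- compute_network_metrics(ch, n_null = 10, n_restarts = 5, seed = 3)
  an <- analyze_cohort(m, n_perm = 200, seed = 1)
  expect_s3_class(an$group_comparisons, "tractnet_comparison")
  expect_s3_class(an$correlations, "tractnet_correlation")
  expect_equal(nrow(an$correlations), 10)  # 5 measures x 2 covariates
  # per-covariate FDR families
  hh <- an$correlations[an$correlations$covariate == "hba1c", ]
  expect_equal(hh$q, bh_fdr(hh$p))
  bad <- dplyr::mutate(m, subject_id = paste0("X", subject_id))
  expect_error(
    analyze_cohort(m, records = dplyr::select(bad, subject_id)),
    "do not match")
})

test_that("null cohorts keep the measure-level false discovery rate low", {
  set.seed(28)
  n_rep <- 60
  flags <- vapply(seq_len(n_rep), function(i) {
    metrics <- tibble::tibble(
      subject_id = sprintf("S%02d", 1:20),
      group = factor(rep(c("control", "patient"), each = 10)),
      gamma = rnorm(20), Q = rnorm(20), lambda = rnorm(20), E = rnorm(20),
      sigma = rnorm(20))
    cmp <- compare_groups(metrics, n_perm = 400, seed = i)
    mean(cmp$q < 0.05)
  }, numeric(1))
  expect_lt(mean(flags), 0.08)
})

test_that("tidiers return plain tibbles with the documented columns", {
  set.seed(29)
  ch <- generate_cohort(small_config(), seed = 4)
  m <- compute_network_metrics(ch, n_null = 10, n_restarts = 5, seed = 4)
  an <- analyze_cohort(m, n_perm = 100, seed = 1)
  tc <- tidy(an$group_comparisons)
  expect_false(inherits(tc, "tractnet_comparison"))
  expect_true(all(c("measure", "mean_control", "mean_patient", "p", "q")
                  %in% names(tc)))
  tr <- tidy(an, which = "correlation")
  expect_true(all(c("measure", "covariate", "r", "p", "q") %in% names(tr)))
  gl <- glance(an)
  expect_true(all(c("n_measures", "corr_n_tests") %in% names(gl)))
})

test_that("autoplot builds ggplot objects for both result types", {
  set.seed(30)
  ch <- generate_cohort(small_config(), seed = 5)
  m <- compute_network_metrics(ch, n_null = 10, n_restarts = 5, seed = 5)
  an <- analyze_cohort(m, n_perm = 100, seed = 1)
  expect_s3_class(autoplot(an$group_comparisons), "ggplot")
  expect_s3_class(autoplot(an$correlations), "ggplot")
})
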