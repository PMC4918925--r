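test_that("config validation rejects degenerate settings", {
  expect_error(cohort_config(lattice_degree = 5), "even")
  expect_error(cohort_config(n_nodes = 10, lattice_degree = 12),
               "degenerate")
  expect_error(cohort_config(shortcut_prob_control = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(weight_scale_patient = 0), "positive")
  expect_error(cohort_config(n_per_group = 0), "n_per_group")
})

test_that("no randomness in topology or weights gives the exact lattice", {
  cfg <- cohort_config(n_per_group = 2, n_nodes = 20, lattice_degree = 4,
                       shortcut_prob_control = 0, shortcut_prob_patient = 0,
                       weight_dispersion = 0, weight_scale_control = 1,
                       weight_scale_patient = 1)
  ch <- generate_cohort(cfg, seed = 1)
  ws <- ch$connectome
  # all subjects identical
  for (w in ws[-1]) expect_identical(w, ws[[1]])
  # exact ring lattice: every node has exactly lattice_degree neighbours,
  # all weights equal
  w <- ws[[1]]
  expect_true(all(rowSums(w > 0) == 4))
  pos <- w[w > 0]
  expect_true(all(pos == pos[1]))
})

test_that("identical config and seed reproduce the identical cohort", {
  cfg <- small_config()
  expect_identical(generate_cohort(cfg, seed = 77),
                   generate_cohort(cfg, seed = 77))
  # different seed gives a different cohort
  expect_false(identical(generate_cohort(cfg, seed = 77),
                         generate_cohort(cfg, seed = 78)))
})

test_that("cohort structure: groups, sex balance, ages, covariates", {
  cfg <- small_config()
  ch <- generate_cohort(cfg, seed = 5)
  expect_equal(nrow(ch), 8)
  expect_equal(as.vector(table(ch$group)), c(4, 4))
  # sex balanced within group at the configured fraction
  expect_equal(sum(ch$sex[ch$group == "control"]), round(0.45 * 4))
  expect_true(all(ch$age >= cfg$age_range[1] & ch$age <= cfg$age_range[2]))
  expect_true(all(is.finite(ch$hba1c)), all(is.finite(ch$fpg)))
  # matrices are valid connectivity matrices
  for (w in ch$connectome) expect_silent(as_connectivity_matrix(w))
})

test_that("more shortcuts in controls raises their efficiency (oracle)", {
  # brute-force Floyd-Warshall efficiency on small ensembles
  set.seed(99)
  eff <- function(p) {
    mean(vapply(1:6, function(i) {
      w <- tractnet:::generate_connectome(24, 4, p, 1, 0.3, log(30), 3)
      oracle_efficiency(w)
    }, numeric(1)))
  }
  expect_gt(eff(0.4), eff(0.05))
})

test_that("streamline-count threshold prunes low-count edges naturally", {
  set.seed(2)
  # strong dispersion pushes many counts below 3
  w_thr <- tractnet:::generate_connectome(40, 6, 0, 1, 1.5, log(5), 3)
  w_all <- withr::with_seed(2,
    tractnet:::generate_connectome(40, 6, 0, 1, 1.5, log(5), 0))
  expect_lt(n_edges(w_thr), n_edges(w_all))
})

test_that("covariate injection hits its target correlation", {
  # independence at target 0
  set.seed(1)
  m <- rnorm(5000)
  g <- generate_covariate(m, 0, seed = 2)
  expect_lt(abs(cor(m, g)), 0.05)
  # near-deterministic at 0.99 and large n
  m <- rnorm(10000)
  g <- generate_covariate(m, 0.99, mean = 5, sd = 2, seed = 3)
  expect_lt(abs(cor(m, g) - 0.99), 0.01)
  expect_equal(mean(g), 5, tolerance = 1e-9)
  expect_equal(sd(g), 2, tolerance = 1e-9)
})

test_that("mean sample correlation over many small draws matches target", {
  set.seed(4)
  m <- rnorm(40)
  rs <- vapply(1:200, function(i) {
    cor(m, generate_covariate(m, -0.53, seed = i))
  }, numeric(1))
  expect_lt(abs(mean(rs) + 0.53), 0.03)
})

test_that("covariate generation guards its preconditions", {
  expect_error(generate_covariate(rep(1, 10), 0.5), "zero variance")
  expect_error(generate_covariate(rnorm(10), 1), "target_r")
  expect_error(generate_covariate(rnorm(2), 0.5), "3 subjects")
})

test_that("partialized injection survives confound adjustment", {
  set.seed(6)
  n <- 2000
  confound <- cbind(a = rnorm(n), b = rnorm(n))
  metric <- confound[, 1] * 2 + rnorm(n)  # metric loaded on the confound
  g <- generate_covariate(metric, -0.5, seed = 7, controls = confound)
  pc <- partial_correlation(metric, g, covariates = confound)
  expect_lt(abs(pc$r + 0.5), 0.06)
})

test_that("weight-scale calibration is the analytic ratio", {
  set.seed(9)
  w <- random_weighted_graph(15, p_edge = 0.5)
  e0 <- global_efficiency(w)
  expect_equal(calibrate_weight_scale(w, e0), 1)
  s <- calibrate_weight_scale(w, 2 * e0)
  expect_equal(s, 2)
  # applying the scale moves pipeline efficiency onto the target exactly
  expect_equal(global_efficiency(s * w), 2 * e0, tolerance = 1e-12)
  expect_error(calibrate_weight_scale(matrix(0, 3, 3), 1), "zero efficiency")
  expect_error(calibrate_weight_scale(w, -1), "positive")
})

test_that("shortcut-probability calibration brackets and bisects", {
  cfg <- cohort_config(n_per_group = 2, n_nodes = 36, lattice_degree = 6,
                       weight_dispersion = 0.3)
  # lambda = 1 is the random end: returned probability is high
  p1 <- calibrate_shortcut_prob(1, cfg, n_null = 10, n_probe = 3,
                                tol = 0.03, max_iter = 8, seed = 2)
  expect_gte(p1, 0.5)
  # higher lambda targets return lower probabilities (monotonicity)
  p_mid <- calibrate_shortcut_prob(1.2, cfg, n_null = 15, n_probe = 4,
                                   tol = 0.02, max_iter = 8, seed = 2)
  p_high <- calibrate_shortcut_prob(1.5, cfg, n_null = 15, n_probe = 4,
                                    tol = 0.02, max_iter = 8, seed = 2)
  expect_lt(p_mid, p1)
  expect_lt(p_high, p_mid)
  # unreachable target errors with the achievable range
  expect_error(
    calibrate_shortcut_prob(50, cfg, n_null = 5, n_probe = 2, seed = 2),
    "achievable range")
})
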