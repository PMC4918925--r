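make_tensor_row <- function(evals, dir = c(1, 0, 0)) {
  R <- tractnet:::rotation_to(dir)
  Dm <- R %*% diag(evals) %*% t(R)
  c(Dm[1, 1], Dm[2, 2], Dm[3, 3], Dm[1, 2], Dm[1, 3], Dm[2, 3])
}

test_that("noiseless signals refit the generating tensor", {
  gt <- gradient_scheme(n_dir = 30)
  evals <- c(1.7e-3, 0.3e-3, 0.2e-3)
  dir <- c(1, 2, 0.5) / sqrt(sum(c(1, 2, 0.5)^2))
  d6 <- make_tensor_row(evals, dir)
  g <- gt$bvecs
  bdes <- gt$bvals * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                           2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                           2 * g[, 2] * g[, 3])
  s <- exp(-as.vector(bdes %*% d6))
  tv <- fit_tensor(matrix(s, 1), gt$bvals, gt$bvecs)
  expect_lt(max(abs(tv$D[1, ] - d6)) / max(abs(d6)), 1e-10)
})

test_that("degenerate schemes and bad signals are rejected or flagged", {
  gt <- gradient_scheme(n_dir = 30)
  expect_error(fit_tensor(matrix(1, 1, 8), rep(0, 8),
                          matrix(0, 8, 3)), "rank deficient|underdetermined")
  expect_error(fit_tensor(matrix(1, 1, 5), c(0, rep(1000, 4)),
                          gt$bvecs[1:5, ]), "at least 7")
  expect_error(fit_tensor(matrix(1, 1, 31), rep(1000, 31), gt$bvecs),
               "b = 0")
  # nonpositive signal flags the voxel invalid, does not error
  s <- matrix(1, 2, 31); s[2, 5] <- -1
  tv <- fit_tensor(s, gt$bvals, gt$bvecs)
  expect_true(tv$valid[1])
  expect_false(tv$valid[2])
  expect_true(all(is.na(tv$D[2, ])))
})

test_that("isotropic tensors give equal eigenvalues and zero FA", {
  d <- 0.7e-3
  tv <- tensor_volume(matrix(c(d, d, d, 0, 0, 0), 1), c(1, 1, 1),
                      c(2, 2, 2))
  eg <- tractnet:::tensor_eigen(tv)
  expect_equal(eg$values[1, ], rep(d, 3), tolerance = 1e-12)
  sc <- tensor_scalars(tv)
  expect_equal(as.numeric(sc$FA), 0, tolerance = 1e-7)
  expect_equal(as.numeric(sc$MD), d)
  expect_equal(as.numeric(sc$AD), d)
  expect_equal(as.numeric(sc$RD), d)
})

test_that("scalar formulas match hand-evaluated eigenvalue expressions", {
  # stick limit
  tv <- tensor_volume(matrix(make_tensor_row(c(1, 0, 0)), 1), c(1, 1, 1),
                      c(1, 1, 1))
  sc <- tensor_scalars(tv)
  expect_equal(as.numeric(sc$FA), 1, tolerance = 1e-12)
  expect_equal(as.numeric(sc$RD), 0, tolerance = 1e-12)

  # prolate white-matter-like tensor: direct evaluation of the FA formula
  lam <- c(1.7e-3, 0.3e-3, 0.2e-3)
  md <- mean(lam)
  fa_direct <- sqrt(3 / 2) * sqrt(sum((lam - md)^2)) / sqrt(sum(lam^2))
  tv <- tensor_volume(matrix(make_tensor_row(lam, c(0, 1, 1)), 1),
                      c(1, 1, 1), c(1, 1, 1))
  sc <- tensor_scalars(tv)
  expect_equal(as.numeric(sc$FA), fa_direct, tolerance = 1e-10)
  expect_equal(fa_direct, 0.8359, tolerance = 1e-4)
  expect_equal(as.numeric(sc$MD), md)
  expect_equal(as.numeric(sc$AD), 1.7e-3)
  expect_equal(as.numeric(sc$RD), 0.25e-3)
})

test_that("FA is invariant to rotation and uniform eigenvalue scaling", {
  set.seed(12)
  lam <- sort(runif(3, 0.1e-3, 2e-3), decreasing = TRUE)
  fa_of <- function(evals, dir) {
    tv <- tensor_volume(matrix(make_tensor_row(evals, dir), 1),
                        c(1, 1, 1), c(1, 1, 1))
    as.numeric(tensor_scalars(tv)$FA)
  }
  base <- fa_of(lam, c(1, 0, 0))
  for (rep in 1:5) {
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    expect_equal(fa_of(lam, dir), base, tolerance = 1e-9)
    expect_equal(fa_of(lam * runif(1, 0.5, 3), dir), base,
                 tolerance = 1e-9)
  }
})

test_that("MD equals trace/3 and negative eigenvalues are clamped", {
  set.seed(13)
  d6 <- make_tensor_row(c(1.5e-3, 0.4e-3, 0.3e-3), c(1, 1, 0))
  tv <- tensor_volume(rbind(d6), c(1, 1, 1), c(1, 1, 1))
  sc <- tensor_scalars(tv)
  expect_equal(as.numeric(sc$MD), (d6[1] + d6[2] + d6[3]) / 3,
               tolerance = 1e-12)
  # a non-PSD fitted tensor gets clamped and flagged
  bad <- c(1e-3, 1e-3, -2e-4, 0, 0, 0)
  tvb <- tensor_volume(rbind(bad), c(1, 1, 1), c(1, 1, 1))
  scb <- tensor_scalars(tvb)
  expect_true(attr(scb, "clamped")[1])
  expect_gte(as.numeric(scb$FA), 0)
  expect_lte(as.numeric(scb$FA), 1)
  expect_gte(as.numeric(scb$RD), 0)
})

test_that("simulate -> fit -> scalars round-trips a phantom exactly", {
  cfg <- bar_phantom_config(grid_shape = c(8, 5, 5))
  ph <- generate_tensor_phantom(cfg)
  tv <- fit_tensor(ph$signals, ph$bvals, ph$bvecs, dim = cfg$grid_shape,
                   voxel_size = cfg$voxel_size)
  sc_fit <- tensor_scalars(tv)
  sc_true <- tensor_scalars(ph$tensors)
  expect_equal(sc_fit$FA, sc_true$FA, tolerance = 1e-8)
  expect_equal(sc_fit$MD, sc_true$MD, tolerance = 1e-8)
})

test_that("phantom rejects non-positive-definite block tensors", {
  expect_error(
    phantom_config(c(4, 4, 4), blocks = list(list(
      bounds = rbind(c(1, 2), c(1, 2), c(1, 2)),
      evals = c(1e-3, -1e-4, 1e-4), dir = c(1, 0, 0)))),
    "positive semidefinite")
})

test_that("isotropic phantom has FA 0 everywhere after refit", {
  cfg <- phantom_config(c(5, 4, 3), noise_sd = 0)
  ph <- generate_tensor_phantom(cfg)
  tv <- fit_tensor(ph$signals, ph$bvals, ph$bvecs, dim = cfg$grid_shape,
                   voxel_size = cfg$voxel_size)
  sc <- tensor_scalars(tv)
  expect_lt(max(sc$FA), 1e-6)
})
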