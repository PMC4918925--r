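# x-oriented prolate field filling the whole grid
uniform_x_field <- function(grid = c(16, 7, 7), voxel = c(2, 2, 2)) {
  cfg <- phantom_config(grid, voxel_size = voxel, blocks = list(
    list(bounds = rbind(c(1, grid[1]), c(1, grid[2]), c(1, grid[3])),
         evals = c(1.7e-3, 0.2e-3, 0.2e-3), dir = c(1, 0, 0))))
  generate_tensor_phantom(cfg)
}

test_that("seed placement is uniform within voxels and reproducible", {
  mask <- array(FALSE, c(3, 3, 3))
  mask[2, 2, 2] <- TRUE
  pts <- seed_points(mask, voxel_size = c(2, 2, 2), seeds_per_voxel = 20,
                     seed = 1)
  expect_equal(nrow(pts), 20)
  expect_true(all(pts[, 1] >= 2 & pts[, 1] <= 4))
  expect_true(all(pts[, 2] >= 2 & pts[, 2] <= 4))
  expect_true(all(pts[, 3] >= 2 & pts[, 3] <= 4))
  expect_identical(pts, seed_points(mask, c(2, 2, 2), 20, seed = 1))
  expect_equal(nrow(seed_points(mask, c(2, 2, 2), 0)), 0)
  expect_error(seed_points(array(FALSE, c(2, 2, 2))), "empty")
})

test_that("a uniform x field yields straight x-spanning streamlines", {
  ph <- uniform_x_field()
  sc <- tensor_scalars(ph$tensors)
  center <- c(16, 7, 7)  # mm, middle of the volume
  sl <- track_streamline(ph$tensors, sc$FA, center)
  expect_false(is.null(sl))
  # straight: y and z never move
  expect_lt(max(abs(sl[, 2] - center[2])), 1e-9)
  expect_lt(max(abs(sl[, 3] - center[3])), 1e-9)
  # spans (nearly) the whole volume along x
  expect_lt(min(sl[, 1]), 2)
  expect_gt(max(sl[, 1]), 30)
  # consecutive spacing equals the step size
  steps <- sqrt(rowSums(diff(sl)^2))
  expect_equal(steps, rep(1, length(steps)), tolerance = 1e-9)
})

test_that("tracking refuses seeds below the FA threshold", {
  ph <- uniform_x_field()
  sc <- tensor_scalars(ph$tensors)
  # low-FA field: scale down anisotropy
  cfg <- phantom_config(c(8, 5, 5), blocks = list(
    list(bounds = rbind(c(1, 8), c(1, 5), c(1, 5)),
         evals = c(0.8e-3, 0.7e-3, 0.65e-3), dir = c(1, 0, 0))))
  ph_low <- generate_tensor_phantom(cfg)
  sc_low <- tensor_scalars(ph_low$tensors)
  expect_lt(max(sc_low$FA), 0.15)
  expect_null(track_streamline(ph_low$tensors, sc_low$FA, c(8, 5, 5)))
  # out-of-volume seed
  expect_null(track_streamline(ph$tensors, sc$FA, c(-5, 5, 5)))
})

test_that("a 90-degree fiber interface terminates tracking", {
  grid <- c(16, 16, 5)
  cfg <- phantom_config(grid, voxel_size = c(1, 1, 1), blocks = list(
    list(bounds = rbind(c(1, 8), c(1, 16), c(1, 5)),
         evals = c(1.7e-3, 0.2e-3, 0.2e-3), dir = c(1, 0, 0)),
    list(bounds = rbind(c(9, 16), c(1, 16), c(1, 5)),
         evals = c(1.7e-3, 0.2e-3, 0.2e-3), dir = c(0, 1, 0))))
  ph <- generate_tensor_phantom(cfg)
  sc <- tensor_scalars(ph$tensors)
  sl <- track_streamline(ph$tensors, sc$FA, c(4.5, 8.5, 2.5))
  # the walk stops at the 90-degree turn instead of following the y fibers
  expect_lte(max(sl[, 1]), 9.5)
  expect_lt(max(abs(sl[, 2] - 8.5)), 1e-9)
})

test_that("streamlines are seed-local: order of seeds never matters", {
  ph <- uniform_x_field()
  sc <- tensor_scalars(ph$tensors)
  eg <- tractnet:::tensor_eigen(ph$tensors)
  seeds <- rbind(c(10, 7, 7), c(20, 5, 5), c(6, 9, 9))
  fwd <- lapply(seq_len(nrow(seeds)), function(i) {
    track_streamline(ph$tensors, sc$FA, seeds[i, ], eigen_cache = eg)
  })
  bwd <- lapply(rev(seq_len(nrow(seeds))), function(i) {
    track_streamline(ph$tensors, sc$FA, seeds[i, ], eigen_cache = eg)
  })
  expect_identical(fwd, rev(bwd))
})

test_that("every retained point passes the FA gate (except terminals)", {
  cfg <- bar_phantom_config(grid_shape = c(14, 7, 7))
  ph <- generate_tensor_phantom(cfg)
  sc <- tensor_scalars(ph$tensors)
  ss <- track_all(ph$tensors, sc$FA, seeds_per_voxel = 3, seed = 2)
  expect_gt(length(ss$streamlines), 0)
  for (sl in ss$streamlines[1:min(20, length(ss$streamlines))]) {
    core <- sl[2:(nrow(sl) - 1), , drop = FALSE]
    fa_vals <- apply(core, 1, function(p) {
      v <- floor(p / cfg$voxel_size) + 1
      sc$FA[v[1], v[2], v[3]]
    })
    expect_true(all(fa_vals > 0.2))
  }
})

test_that("an isotropic phantom yields no streamlines", {
  cfg <- phantom_config(c(6, 6, 6))
  ph <- generate_tensor_phantom(cfg)
  sc <- tensor_scalars(ph$tensors)
  mask <- array(TRUE, c(6, 6, 6))
  ss <- track_all(ph$tensors, sc$FA, mask = mask, seeds_per_voxel = 2,
                  seed = 1)
  expect_equal(length(ss$streamlines), 0)
})

test_that("seed density scales the retained count about linearly", {
  cfg <- bar_phantom_config(grid_shape = c(14, 7, 7))
  ph <- generate_tensor_phantom(cfg)
  sc <- tensor_scalars(ph$tensors)
  n1 <- length(track_all(ph$tensors, sc$FA, seeds_per_voxel = 4,
                         seed = 3)$streamlines)
  n2 <- length(track_all(ph$tensors, sc$FA, seeds_per_voxel = 8,
                         seed = 3)$streamlines)
  expect_gt(n2 / n1, 1.7)
  expect_lt(n2 / n1, 2.3)
})

test_that("halving the step moves straight-phantom endpoints < 1 voxel", {
  ph <- uniform_x_field()
  sc <- tensor_scalars(ph$tensors)
  s1 <- track_streamline(ph$tensors, sc$FA, c(16, 7, 7), step_mm = 1)
  s2 <- track_streamline(ph$tensors, sc$FA, c(16, 7, 7), step_mm = 0.5)
  ends <- function(s) c(min(s[, 1]), max(s[, 1]))
  expect_lt(max(abs(ends(s1) - ends(s2))), 2)  # one 2 mm voxel edge
})
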