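#' Deterministic gradient scheme
#'
#' A b = 0 measurement followed by `n_dir` directions spread over the
#' sphere by the spherical Fibonacci spiral - a deterministic stand-in for
#' a scanner's 30-direction table.
#'
#' @param n_dir Number of diffusion-weighted directions (default 30).
#' @param b b-value of the weighted measurements (s/mm^2, default 1000).
#' @return List with `bvals` (length `n_dir + 1`) and `bvecs`
#'   (`(n_dir + 1) x 3`, first row zero).
#' @export
gradient_scheme <- function(n_dir = 30, b = 1000) {
  i <- seq_len(n_dir) - 0.5
  z <- 1 - 2 * i / n_dir
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  g <- cbind(r * cos(phi), r * sin(phi), z)
  list(bvals = c(0, rep(b, n_dir)), bvecs = rbind(c(0, 0, 0), g))
}

# rotation taking (1,0,0) onto `dir` (any orthonormal completion will do:
# the tensor only depends on the principal axis for axially symmetric
# eigenvalues, and field specs supply the principal axis).
rotation_to <- function(dir) {
  e1 <- dir / sqrt(sum(dir^2))
  helper <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- helper - sum(helper * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  cbind(e1, e2, e3)
}

#' Tensor phantom configuration
#'
#' Describes a rectangular grid of diffusion tensors built from piecewise
#' constant blocks. Each block assigns eigenvalues and a principal
#' direction (and optionally a region label) to a box of voxels; later
#' blocks override earlier ones. The default background is isotropic with
#' the `background_eval` diffusivity.
#'
#' @param grid_shape Integer voxel counts `c(nx, ny, nz)`.
#' @param voxel_size Voxel edge lengths in mm.
#' @param blocks List of blocks; each is a list with `bounds` (3 x 2 matrix
#'   of inclusive voxel index ranges), `evals` (three non-negative
#'   eigenvalues, descending), `dir` (principal axis), optional `label`
#'   (positive integer region id).
#' @param background_eval Isotropic background diffusivity (mm^2/s).
#' @param noise_sd Gaussian noise sd added to the signals (signal units;
#'   baseline S0 = 1).
#' @param S0 Baseline signal.
#' @param seed Integer seed for the noise.
#' @return List of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape, voxel_size = c(2, 2, 2),
                           blocks = list(), background_eval = 0.7e-3,
                           noise_sd = 0, S0 = 1, seed = 1) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1),
            length(voxel_size) == 3, all(voxel_size > 0), noise_sd >= 0)
  for (blk in blocks) {
    if (any(blk$evals < 0)) {
      stop("requested tensor is not positive semidefinite: ",
           "negative eigenvalue in block", call. = FALSE)
    }
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size), blocks = blocks,
                 background_eval = background_eval, noise_sd = noise_sd,
                 S0 = S0, seed = seed),
            class = "phantom_config")
}

#' Two-region bar phantom
#'
#' A prolate "fiber bar" running along x through an isotropic background,
#' with labelled terminal regions at the two ends - the standard fixture
#' for end-to-end tracking and connectome tests.
#'
#' @param grid_shape Voxel counts (default `c(20, 9, 9)`).
#' @param bar_evals Eigenvalues of the bar tensor.
#' @param ... Passed to [phantom_config()].
#' @return A [phantom_config()].
#' @export
bar_phantom_config <- function(grid_shape = c(20, 9, 9),
                               bar_evals = c(1.7e-3, 0.2e-3, 0.2e-3), ...) {
  mid <- function(n) floor((n + 1) / 2) + c(-1, 1)
  ymid <- mid(grid_shape[2]); zmid <- mid(grid_shape[3])
  bar <- list(bounds = rbind(c(1, grid_shape[1]), ymid, zmid),
              evals = bar_evals, dir = c(1, 0, 0))
  left <- list(bounds = rbind(c(1, 2), ymid, zmid),
               evals = bar_evals, dir = c(1, 0, 0), label = 1L)
  right <- list(bounds = rbind(grid_shape[1] - c(1, 0), ymid, zmid),
                evals = bar_evals, dir = c(1, 0, 0), label = 2L)
  phantom_config(grid_shape = grid_shape, blocks = list(bar, left, right),
                 ...)
}

#' Generate a tensor phantom
#'
#' Realizes a [phantom_config()] as (i) a ground-truth [tensor_volume()],
#' (ii) an integer label volume marking terminal regions, and (iii) a
#' diffusion-weighted signal set `S_k = S0 * exp(-b_k g_k' D g_k)` (plus
#' optional Gaussian noise) for a stated gradient scheme, ready for
#' [fit_tensor()].
#'
#' @param config A [phantom_config()].
#' @param gradients Gradient scheme from [gradient_scheme()].
#' @return List with `tensors` (tensor_volume), `labels` (3-D integer
#'   array), `signals` (`n_voxels x k` matrix), `bvals`, `bvecs`.
#' @export
generate_tensor_phantom <- function(config,
                                    gradients = gradient_scheme()) {
  stopifnot(inherits(config, "phantom_config"))
  shape <- config$grid_shape
  n_vox <- prod(shape)
  iso <- config$background_eval
  D <- matrix(rep(c(iso, iso, iso, 0, 0, 0), each = n_vox), n_vox, 6)
  labels <- array(0L, shape)

  vox_index <- array(seq_len(n_vox), shape)
  for (blk in config$blocks) {
    b <- blk$bounds
    R <- rotation_to(blk$dir)
    Dm <- R %*% diag(blk$evals) %*% t(R)
    d6 <- c(Dm[1, 1], Dm[2, 2], Dm[3, 3], Dm[1, 2], Dm[1, 3], Dm[2, 3])
    sel <- vox_index[b[1, 1]:b[1, 2], b[2, 1]:b[2, 2], b[3, 1]:b[3, 2]]
    D[as.vector(sel), ] <- matrix(d6, length(sel), 6, byrow = TRUE)
    if (!is.null(blk$label)) labels[as.vector(sel)] <- as.integer(blk$label)
  }

  g <- gradients$bvecs
  bdes <- gradients$bvals * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                                  2 * g[, 1] * g[, 2],
                                  2 * g[, 1] * g[, 3],
                                  2 * g[, 2] * g[, 3])
  signals <- config$S0 * exp(-D %*% t(bdes))
  if (config$noise_sd > 0) {
    signals <- signals + withr::with_seed(
      config$seed, matrix(rnorm(length(signals), sd = config$noise_sd),
                          nrow(signals)))
  }
  list(tensors = tensor_volume(D, dim = shape,
                               voxel_size = config$voxel_size),
       labels = labels,
       signals = signals,
       bvals = gradients$bvals, bvecs = gradients$bvecs)
}
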