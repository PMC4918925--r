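#' Random seed points within masked voxels
#'
#' Places `seeds_per_voxel` uniform random points inside every masked voxel
#' (volume mm coordinates: voxel `(i, j, k)` spans
#' `[(i-1) * vs, i * vs)` per axis).
#'
#' @param mask 3-D logical array of seed voxels (nonempty).
#' @param voxel_size Voxel edge lengths in mm.
#' @param seeds_per_voxel Seeds per voxel (default 20; 0 gives an empty
#'   set).
#' @param seed Optional integer seed for reproducibility.
#' @return `n x 3` matrix of seed coordinates (mm).
#' @export
seed_points <- function(mask, voxel_size = c(1, 1, 1), seeds_per_voxel = 20,
                        seed = NULL) {
  vox <- which(mask, arr.ind = TRUE)
  if (nrow(vox) == 0) stop("mask is empty", call. = FALSE)
  if (seeds_per_voxel == 0) {
    return(matrix(numeric(0), 0, 3,
                  dimnames = list(NULL, c("x", "y", "z"))))
  }
  run <- function() {
    n <- nrow(vox) * seeds_per_voxel
    lower <- (vox[rep(seq_len(nrow(vox)), each = seeds_per_voxel), ,
                  drop = FALSE] - 1)
    offs <- matrix(runif(3 * n), n, 3)
    sweep(lower + offs, 2, voxel_size, `*`)
  }
  pts <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  colnames(pts) <- c("x", "y", "z")
  pts
}

# voxel index (1-based) of a point; NA row when out of bounds
point_voxel <- function(p, dim, voxel_size) {
  v <- floor(p / voxel_size) + 1
  if (any(v < 1) || any(v > dim)) return(NULL)
  as.integer(v)
}

vox_linear <- function(v, dim) {
  v[1] + (v[2] - 1) * dim[1] + (v[3] - 1) * dim[1] * dim[2]
}

# one-directional Euler walk; returns matrix of points beyond the seed
walk_one_way <- function(start, dir0, v1, fa_arr, dim, voxel_size, step,
                         fa_stop, cos_stop, max_steps) {
  pts <- matrix(NA_real_, max_steps, 3)
  p <- start
  dir_prev <- dir0
  n_out <- 0
  for (s in seq_len(max_steps)) {
    p_new <- p + step * dir_prev
    v <- point_voxel(p_new, dim, voxel_size)
    if (is.null(v)) break
    iv <- vox_linear(v, dim)
    fa_v <- fa_arr[iv]
    if (!is.finite(fa_v) || fa_v <= fa_stop) break
    e1 <- v1[iv, ]
    if (any(!is.finite(e1))) break
    if (sum(e1 * dir_prev) < 0) e1 <- -e1  # keep heading
    if (sum(e1 * dir_prev) < cos_stop) break  # turn >= angle threshold
    n_out <- n_out + 1
    pts[n_out, ] <- p_new
    p <- p_new
    dir_prev <- e1
  }
  pts[seq_len(n_out), , drop = FALSE]
}

#' Track a single deterministic streamline
#'
#' Bidirectional Euler integration along the principal eigenvector of the
#' nearest-neighbour voxel tensor, starting from a seed point. The
#' eigenvector sign is chosen to continue the previous heading.
#' Propagation stops when the local FA drops to `fa_stop` or below, the
#' turn between successive step directions reaches `angle_stop_deg`, or
#' the point leaves the volume. Returns `NULL` when the seed voxel itself
#' fails the FA criterion (or has a non-finite tensor).
#'
#' @param tv [tensor_volume()] (or a precomputed eigensystem via
#'   `tractnet:::tensor_eigen`).
#' @param fa 3-D FA array matching the grid (from [tensor_scalars()]).
#' @param seed_point Length-3 numeric, mm coordinates.
#' @param step_mm Euler step; default half the smallest voxel edge.
#' @param fa_stop FA stopping threshold (default 0.2, tracking requires
#'   FA > 0.2).
#' @param angle_stop_deg Per-step turning threshold in degrees (default
#'   30).
#' @param max_steps Cap per direction.
#' @param eigen_cache Optional precomputed `tensor_eigen(tv)` result.
#' @return `n x 3` matrix of ordered points (>= 2 rows), or `NULL`.
#' @export
track_streamline <- function(tv, fa, seed_point,
                             step_mm = 0.5 * min(tv$voxel_size),
                             fa_stop = 0.2, angle_stop_deg = 30,
                             max_steps = 2000, eigen_cache = NULL) {
  dim <- tv$dim
  voxel_size <- tv$voxel_size
  v <- point_voxel(seed_point, dim, voxel_size)
  if (is.null(v)) return(NULL)
  iv <- vox_linear(v, dim)
  if (!is.finite(fa[iv]) || fa[iv] <= fa_stop) return(NULL)
  if (is.null(eigen_cache)) eigen_cache <- tensor_eigen(tv)
  e1 <- eigen_cache$v1[iv, ]
  if (any(!is.finite(e1))) return(NULL)
  cos_stop <- cos(angle_stop_deg * pi / 180)
  fwd <- walk_one_way(seed_point, e1, eigen_cache$v1, fa, dim, voxel_size,
                      step_mm, fa_stop, cos_stop, max_steps)
  bwd <- walk_one_way(seed_point, -e1, eigen_cache$v1, fa, dim, voxel_size,
                      step_mm, fa_stop, cos_stop, max_steps)
  pts <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
               matrix(seed_point, 1, 3), fwd)
  if (nrow(pts) < 2) return(NULL)
  colnames(pts) <- c("x", "y", "z")
  pts
}

#' Whole-volume deterministic tractography
#'
#' Seeds every masked voxel with [seed_points()], tracks each seed with
#' [track_streamline()], and keeps streamlines of at least `min_steps`
#' steps. The returned set records its provenance (seed count, thresholds,
#' step size).
#'
#' @inheritParams track_streamline
#' @param mask 3-D logical array of seed voxels; default: FA above
#'   `fa_stop`.
#' @param seeds_per_voxel Seeds per masked voxel (default 20).
#' @param min_steps Minimum retained length in steps (default 2, i.e. 3
#'   points).
#' @param seed Integer seed for the random seed placement.
#' @return Object of class `streamline_set`: list with `streamlines` (list
#'   of point matrices) and `provenance`.
#' @export
track_all <- function(tv, fa, mask = NULL, seeds_per_voxel = 20,
                      step_mm = 0.5 * min(tv$voxel_size), fa_stop = 0.2,
                      angle_stop_deg = 30, min_steps = 2, max_steps = 2000,
                      seed = 1) {
  if (is.null(mask)) mask <- array(is.finite(fa) & fa > fa_stop, tv$dim)
  pts <- seed_points(mask, tv$voxel_size, seeds_per_voxel, seed = seed)
  eg <- tensor_eigen(tv)
  keep <- list()
  for (i in seq_len(nrow(pts))) {
    sl <- track_streamline(tv, fa, pts[i, ], step_mm = step_mm,
                           fa_stop = fa_stop,
                           angle_stop_deg = angle_stop_deg,
                           max_steps = max_steps, eigen_cache = eg)
    if (!is.null(sl) && nrow(sl) >= min_steps + 1) {
      keep[[length(keep) + 1]] <- sl
    }
  }
  structure(list(
    streamlines = keep,
    provenance = list(n_seeds = nrow(pts), seeds_per_voxel = seeds_per_voxel,
                      fa_stop = fa_stop, angle_stop_deg = angle_stop_deg,
                      step_mm = step_mm, min_steps = min_steps,
                      voxel_size = tv$voxel_size, dim = tv$dim)),
    class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat("Streamline set:", length(x$streamlines), "streamlines from",
      x$provenance$n_seeds, "seeds\n")
  invisible(x)
}

#' Tidy a streamline set
#'
#' @param x A `streamline_set`.
#' @param ... Unused.
#' @return Tibble with `streamline_id`, `point_index`, `x`, `y`, `z`.
#' @export
as_tibble.streamline_set <- function(x, ...) {
  purrr::imap_dfr(x$streamlines, function(m, i) {
    tibble::tibble(streamline_id = i, point_index = seq_len(nrow(m)),
                   x = m[, 1], y = m[, 2], z = m[, 3])
  })
}
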