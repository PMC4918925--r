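#' Terminal region labels of a streamline
#'
#' Looks up the parcellation labels of the voxels containing the two
#' terminal points. Returns `NULL` when either terminal lies outside the
#' volume, in background (label 0), or both terminals fall in the same
#' region (self-connections are excluded).
#'
#' @param streamline `n x 3` matrix of points (mm).
#' @param labels 3-D integer label array (0 = background).
#' @param voxel_size Voxel edge lengths in mm.
#' @return Integer pair `c(low, high)` in canonical order, or `NULL`.
#' @export
endpoint_labels <- function(streamline, labels, voxel_size = c(1, 1, 1)) {
  dim <- base::dim(labels)
  v_a <- point_voxel(streamline[1, ], dim, voxel_size)
  v_b <- point_voxel(streamline[nrow(streamline), ], dim, voxel_size)
  if (is.null(v_a) || is.null(v_b)) return(NULL)
  la <- labels[v_a[1], v_a[2], v_a[3]]
  lb <- labels[v_b[1], v_b[2], v_b[3]]
  if (la == 0 || lb == 0 || la == lb) return(NULL)
  c(min(la, lb), max(la, lb))
}

#' Build a fiber-density connectivity matrix from streamlines
#'
#' Counts streamlines per region pair (terminal voxels only), zeroes pairs
#' with fewer than `min_streamlines` counts (the >= 3 rule against
#' false-positive edges), and divides the surviving counts by the total
#' number of streamlines in the whole set - including streamlines later
#' discarded for background endpoints or by the threshold - giving fiber
#' densities.
#'
#' @param ss A `streamline_set` from [track_all()] (or a plain list of
#'   point matrices); must be nonempty.
#' @param labels 3-D integer label array.
#' @param voxel_size Voxel edge lengths in mm (taken from the set's
#'   provenance when available).
#' @param min_streamlines Minimum count for an edge to survive (default 3).
#' @param n_regions Matrix size; defaults to the maximum label present.
#' @param region_names Optional region names for the dimnames.
#' @return Symmetric connectivity matrix with attribute
#'   `total_streamlines`.
#' @export
build_connectome <- function(ss, labels, voxel_size = NULL,
                             min_streamlines = 3, n_regions = NULL,
                             region_names = NULL) {
  sls <- if (inherits(ss, "streamline_set")) ss$streamlines else ss
  if (length(sls) == 0) stop("streamline set is empty", call. = FALSE)
  if (is.null(voxel_size)) {
    voxel_size <- if (inherits(ss, "streamline_set")) {
      ss$provenance$voxel_size
    } else c(1, 1, 1)
  }
  if (is.null(n_regions)) n_regions <- max(labels)
  if (n_regions < 1) stop("label volume contains no regions", call. = FALSE)
  counts <- matrix(0L, n_regions, n_regions)
  for (sl in sls) {
    pr <- endpoint_labels(sl, labels, voxel_size)
    if (!is.null(pr)) counts[pr[1], pr[2]] <- counts[pr[1], pr[2]] + 1L
  }
  counts[counts < min_streamlines] <- 0L
  total <- length(sls)
  w <- (counts + t(counts)) / total
  if (is.null(region_names)) region_names <- paste0("R", seq_len(n_regions))
  dimnames(w) <- list(region_names, region_names)
  attr(w, "total_streamlines") <- total
  w
}
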