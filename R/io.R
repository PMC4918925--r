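#' Write streamlines as tab-separated text
#'
#' Plain-text streamline dialect: columns `streamline_id`, `point_index`,
#' `x`, `y`, `z` (mm).
#'
#' @param ss `streamline_set` or list of point matrices.
#' @param path Output path.
#' @export
write_streamlines_tsv <- function(ss, path) {
  readr::write_tsv(as_tibble.streamline_set(
    if (inherits(ss, "streamline_set")) ss
    else structure(list(streamlines = ss), class = "streamline_set")), path)
  invisible(path)
}

#' @rdname write_streamlines_tsv
#' @param voxel_size Voxel size recorded in the returned set's provenance.
#' @export
read_streamlines_tsv <- function(path, voxel_size = c(1, 1, 1)) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  sls <- df |>
    dplyr::arrange(.data$streamline_id, .data$point_index) |>
    dplyr::group_by(.data$streamline_id) |>
    dplyr::group_map(function(g, key) {
      m <- as.matrix(g[, c("x", "y", "z")])
      rownames(m) <- NULL
      m
    })
  structure(list(streamlines = sls,
                 provenance = list(n_seeds = NA_integer_,
                                   voxel_size = voxel_size)),
            class = "streamline_set")
}

#' Write streamlines in TrackVis TRK format
#'
#' Minimal TRK v2 writer: 1000-byte header with grid dimensions and voxel
#' size honored, no per-point scalars or per-track properties; point
#' coordinates stored in mm. (TRK is a binary format; use
#' [write_streamlines_tsv()] for a text interchange.)
#'
#' @param ss `streamline_set` (uses its provenance for dim / voxel size) or
#'   list of point matrices.
#' @param path Output path.
#' @param dim Grid dimensions (required if not in provenance).
#' @param voxel_size Voxel size in mm.
#' @export
write_trk <- function(ss, path, dim = NULL, voxel_size = NULL) {
  sls <- if (inherits(ss, "streamline_set")) ss$streamlines else ss
  prov <- if (inherits(ss, "streamline_set")) ss$provenance else list()
  if (is.null(dim)) dim <- prov$dim %||% c(0L, 0L, 0L)
  if (is.null(voxel_size)) voxel_size <- prov$voxel_size %||% c(1, 1, 1)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("TRACK", con, nchars = 5, eos = NULL)
  writeBin(raw(1), con)
  writeBin(as.integer(dim), con, size = 2)            # dim, short[3]
  writeBin(as.numeric(voxel_size), con, size = 4)     # voxel_size float[3]
  writeBin(rep(0, 3), con, size = 4)                  # origin
  writeBin(0L, con, size = 2)                         # n_scalars
  writeBin(raw(200), con)                             # scalar names
  writeBin(0L, con, size = 2)                         # n_properties
  writeBin(raw(200), con)                             # property names
  m <- diag(4); m[1, 1] <- voxel_size[1]; m[2, 2] <- voxel_size[2]
  m[3, 3] <- voxel_size[3]
  writeBin(as.numeric(t(m)), con, size = 4)           # vox_to_ras
  writeBin(raw(444), con)                             # reserved
  writeChar("LPS", con, nchars = 3, eos = NULL)
  writeBin(raw(1), con)                               # voxel_order[4]
  writeBin(raw(4), con)                               # pad2
  writeBin(c(1, 0, 0, 0, 1, 0), con, size = 4)        # orientation
  writeBin(raw(2), con)                               # pad1
  writeBin(raw(6), con)                               # invert/swap flags
  writeBin(length(sls), con, size = 4)                # n_count
  writeBin(2L, con, size = 4)                         # version
  writeBin(1000L, con, size = 4)                      # hdr_size
  for (sl in sls) {
    writeBin(nrow(sl), con, size = 4)
    writeBin(as.numeric(t(sl)), con, size = 4)
  }
  invisible(path)
}

#' Read a TrackVis TRK streamline file
#'
#' @param path TRK file written by [write_trk()] or TrackVis-compatible
#'   tools (no scalars/properties supported).
#' @return `streamline_set` with dim/voxel size from the header.
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 5, useBytes = TRUE)
  if (!identical(magic, "TRACK")) stop("not a TRK file", call. = FALSE)
  readBin(con, raw(), 1)
  dim <- readBin(con, integer(), 3, size = 2)
  voxel_size <- readBin(con, numeric(), 3, size = 4)
  seek(con, 36)  # past origin
  n_scalars <- readBin(con, integer(), 1, size = 2)
  seek(con, 238)
  n_properties <- readBin(con, integer(), 1, size = 2)
  if (n_scalars != 0 || n_properties != 0) {
    stop("TRK files with scalars/properties are not supported",
         call. = FALSE)
  }
  seek(con, 988)
  n_count <- readBin(con, integer(), 1, size = 4)
  version <- readBin(con, integer(), 1, size = 4)
  hdr_size <- readBin(con, integer(), 1, size = 4)
  if (hdr_size != 1000) stop("unexpected TRK header size", call. = FALSE)
  sls <- vector("list", n_count)
  for (i in seq_len(n_count)) {
    np <- readBin(con, integer(), 1, size = 4)
    pts <- matrix(readBin(con, numeric(), 3 * np, size = 4), np, 3,
                  byrow = TRUE)
    colnames(pts) <- c("x", "y", "z")
    sls[[i]] <- pts
  }
  structure(list(streamlines = sls,
                 provenance = list(dim = dim, voxel_size = voxel_size,
                                   trk_version = version)),
            class = "streamline_set")
}

#' NIfTI volume IO
#'
#' Thin wrappers over RNifti for the volumes the pipeline exchanges:
#' scalar/label 3-D volumes and 4-D tensor-component volumes.
#'
#' @param x 3-D or 4-D array.
#' @param path File path (`.nii` / `.nii.gz`).
#' @param voxel_size Voxel edge lengths in mm.
#' @export
write_nifti_volume <- function(x, path, voxel_size = c(1, 1, 1)) {
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- c(voxel_size, rep(1, length(base::dim(x)) - 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_volume
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  structure(as.array(img), voxel_size = RNifti::pixdim(img)[1:3])
}

#' Write a tensor volume as NIfTI plus gradient text files
#'
#' The six tensor components go into a 4-D volume (x, y, z, component) in
#' the order Dxx, Dyy, Dzz, Dxy, Dxz, Dyz.
#'
#' @param tv [tensor_volume()].
#' @param path NIfTI output path.
#' @export
write_tensor_nifti <- function(tv, path) {
  arr <- array(tv$D, c(tv$dim, 6))
  write_nifti_volume(arr, path, voxel_size = tv$voxel_size)
}

#' @rdname write_tensor_nifti
#' @export
read_tensor_nifti <- function(path) {
  arr <- read_nifti_volume(path)
  vs <- attr(arr, "voxel_size")
  d <- base::dim(arr)
  tensor_volume(matrix(arr, prod(d[1:3]), 6), dim = d[1:3], voxel_size = vs)
}

#' FSL-style gradient table IO
#'
#' `bval`: one space-separated row of b-values. `bvec`: three rows (x, y,
#' z components), one column per measurement, unit vectors.
#'
#' @param bvals Numeric b-values.
#' @param bvecs `k x 3` gradient direction matrix.
#' @param bval_path,bvec_path Output paths.
#' @export
write_gradients <- function(bvals, bvecs, bval_path, bvec_path) {
  writeLines(paste(format(bvals, trim = TRUE), collapse = " "), bval_path)
  writeLines(apply(t(bvecs), 1, function(r) {
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")
  }), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' @rdname write_gradients
#' @export
read_gradients <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  v <- do.call(rbind, lapply(readLines(bvec_path), function(l) {
    scan(text = l, quiet = TRUE)
  }))
  list(bvals = bvals, bvecs = t(v))
}
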