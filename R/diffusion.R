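#' Construct a tensor volume
#'
#' A tensor volume stores one symmetric diffusion tensor per voxel as six
#' unique components (order `Dxx, Dyy, Dzz, Dxy, Dxz, Dyz`, units mm^2/s)
#' in an `n_voxels x 6` matrix, plus the grid shape and voxel size. Voxels
#' can be flagged invalid (e.g. non-positive signals); their rows are NA.
#'
#' @param D `n_voxels x 6` numeric matrix of tensor components, voxels in
#'   column-major grid order.
#' @param dim Integer grid shape `c(nx, ny, nz)`.
#' @param voxel_size Numeric voxel edge lengths in mm, length 3.
#' @param valid Logical vector flagging usable voxels.
#' @return Object of class `tensor_volume`.
#' @export
tensor_volume <- function(D, dim, voxel_size, valid = NULL) {
  stopifnot(is.matrix(D), ncol(D) == 6, prod(dim) == nrow(D),
            length(voxel_size) == 3, all(voxel_size > 0))
  if (is.null(valid)) valid <- stats::complete.cases(D)
  structure(list(D = D, dim = as.integer(dim),
                 voxel_size = as.numeric(voxel_size), valid = valid),
            class = "tensor_volume")
}

# 3x3 symmetric matrix from a 6-component row
tensor_from_row <- function(d6) {
  matrix(c(d6[1], d6[4], d6[5],
           d6[4], d6[2], d6[6],
           d6[5], d6[6], d6[3]), 3, 3)
}

#' Fit diffusion tensors by log-linear least squares
#'
#' Per voxel, solves `ln S_k = ln S0 - b_k g_k' D g_k` as an ordinary
#' least-squares problem in the seven unknowns (log baseline plus six
#' tensor components). Voxels with any non-positive signal are flagged
#' invalid and excluded downstream rather than fitted.
#'
#' @param signals `n_voxels x n_measurements` matrix of diffusion-weighted
#'   signals (voxels in column-major grid order), or a 4-D array
#'   `(nx, ny, nz, k)`.
#' @param bvals Numeric vector of b-values (s/mm^2), at least one equal
#'   to 0; at least 7 measurements in total.
#' @param bvecs `n_measurements x 3` matrix of unit gradient directions.
#' @param dim Grid shape; taken from the array when `signals` is 4-D.
#' @param voxel_size Voxel edge lengths in mm.
#' @return A [tensor_volume()].
#' @export
fit_tensor <- function(signals, bvals, bvecs, dim = NULL,
                       voxel_size = c(1, 1, 1)) {
  if (is.array(signals) && length(base::dim(signals)) == 4) {
    dim <- base::dim(signals)[1:3]
    signals <- matrix(signals, ncol = base::dim(signals)[4])
  }
  if (is.null(dim)) dim <- c(nrow(signals), 1L, 1L)
  k <- length(bvals)
  if (ncol(signals) != k || nrow(bvecs) != k) {
    stop("signals, bvals and bvecs disagree on the number of measurements",
         call. = FALSE)
  }
  if (k < 7) stop("need at least 7 measurements to fit 7 unknowns",
                  call. = FALSE)
  if (!any(bvals == 0)) stop("need at least one b = 0 measurement",
                             call. = FALSE)
  g <- bvecs
  X <- cbind(1, -bvals * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                               2 * g[, 1] * g[, 2],
                               2 * g[, 1] * g[, 3],
                               2 * g[, 2] * g[, 3]))
  if (qr(X)$rank < 7) {
    stop("gradient scheme is degenerate: design matrix is rank deficient ",
         "(b = 0 only input is underdetermined)", call. = FALSE)
  }
  valid <- apply(signals, 1, function(s) all(is.finite(s)) && all(s > 0))
  D <- matrix(NA_real_, nrow(signals), 6)
  if (any(valid)) {
    beta <- qr.coef(qr(X), t(log(signals[valid, , drop = FALSE])))
    D[valid, ] <- t(beta[-1, , drop = FALSE])
  }
  tensor_volume(D, dim = dim, voxel_size = voxel_size, valid = valid)
}

# Eigen-decompose every valid voxel. Returns eigenvalues sorted descending
# (n_vox x 3, negatives clamped to 0 with a `clamped` flag) and the
# principal eigenvector (n_vox x 3).
tensor_eigen <- function(tv) {
  n <- nrow(tv$D)
  ev <- matrix(NA_real_, n, 3)
  v1 <- matrix(NA_real_, n, 3)
  clamped <- logical(n)
  for (i in which(tv$valid)) {
    e <- eigen(tensor_from_row(tv$D[i, ]), symmetric = TRUE)
    lam <- e$values  # already decreasing
    if (any(lam < 0)) clamped[i] <- TRUE
    ev[i, ] <- pmax(lam, 0)
    v1[i, ] <- e$vectors[, 1]
  }
  list(values = ev, v1 = v1, clamped = clamped)
}

#' Scalar diffusion maps from a tensor volume
#'
#' Computes the four standard tensor invariants per voxel from eigenvalues
#' `l1 >= l2 >= l3` (negative eigenvalues from noisy fits are clamped to 0
#' and the voxel flagged): mean diffusivity `MD = (l1+l2+l3)/3`, axial
#' diffusivity `AD = l1`, radial diffusivity `RD = (l2+l3)/2`, and
#' fractional anisotropy
#' `FA = sqrt(3/2) * sqrt(sum((li - MD)^2)) / sqrt(sum(li^2))`
#' (0 for an all-zero tensor). FA is always in `[0, 1]`.
#'
#' @param tv A [tensor_volume()].
#' @return Named list of 3-D arrays `FA`, `MD`, `AD`, `RD` (grid shape of
#'   `tv`; NA at invalid voxels), with attribute `clamped` flagging voxels
#'   whose eigenvalues were clamped.
#' @export
tensor_scalars <- function(tv) {
  stopifnot(inherits(tv, "tensor_volume"))
  eg <- tensor_eigen(tv)
  lam <- eg$values
  md <- rowMeans(lam)
  ad <- lam[, 1]
  rd <- (lam[, 2] + lam[, 3]) / 2
  ss <- rowSums(lam^2)
  fa <- ifelse(ss > 0,
               sqrt(3 / 2) * sqrt(rowSums((lam - md)^2)) / sqrt(ss), 0)
  fa[!tv$valid] <- NA_real_
  shape <- tv$dim
  out <- list(FA = array(pmin(pmax(fa, 0), 1), shape),
              MD = array(md, shape),
              AD = array(ad, shape),
              RD = array(rd, shape))
  attr(out, "clamped") <- array(eg$clamped, shape)
  out
}
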