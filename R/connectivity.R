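#' Validate a connectivity matrix
#'
#' A structural connectome is stored as a plain numeric matrix: square,
#' symmetric, non-negative, zero diagonal. Row/column names, when present,
#' carry the region labels. This checks those invariants and returns the
#' matrix (with the diagonal zeroed) so downstream metric functions can
#' assume a clean input.
#'
#' @param w Numeric square matrix of edge weights (fiber densities).
#' @param tol Tolerance for the symmetry check.
#' @return The validated matrix, diagonal set to zero.
#' @export
as_connectivity_matrix <- function(w, tol = 1e-10) {
  if (!is.matrix(w) || !is.numeric(w)) {
    stop("`w` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(w) != ncol(w)) {
    stop("`w` must be square; got ", nrow(w), " x ", ncol(w), call. = FALSE)
  }
  if (anyNA(w) || any(!is.finite(w))) {
    stop("`w` contains missing or non-finite weights", call. = FALSE)
  }
  if (any(w < 0)) {
    stop("`w` contains negative weights; fiber densities must be >= 0",
         call. = FALSE)
  }
  if (max(abs(w - t(w))) > tol * max(1, max(abs(w)))) {
    stop("`w` is not symmetric", call. = FALSE)
  }
  diag(w) <- 0
  w
}

#' Number of undirected edges of a connectivity matrix
#' @param w Connectivity matrix.
#' @return Count of node pairs with positive weight.
#' @export
n_edges <- function(w) {
  w <- as_connectivity_matrix(w)
  sum(w[upper.tri(w)] > 0)
}

#' Total connection strength
#'
#' Sum of all edge weights (each undirected edge counted once), used as a
#' per-subject confound in the partial-correlation analysis.
#'
#' @param w Connectivity matrix.
#' @return Non-negative scalar.
#' @export
total_strength <- function(w) {
  w <- as_connectivity_matrix(w)
  sum(w[upper.tri(w)])
}

#' Write a connectivity matrix to CSV
#'
#' One row per region with a header row of region labels, the on-disk
#' interchange format for single-subject connectomes.
#'
#' @param w Connectivity matrix (row/column names used as region labels;
#'   defaults to `R1..Rn`).
#' @param path Output file path.
#' @export
write_connectome_csv <- function(w, path) {
  w <- as_connectivity_matrix(w)
  if (is.null(rownames(w))) {
    rownames(w) <- colnames(w) <- paste0("R", seq_len(nrow(w)))
  }
  df <- tibble::as_tibble(w, .name_repair = "minimal")
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a connectivity matrix from CSV
#' @param path File written by [write_connectome_csv()].
#' @return Connectivity matrix with region labels as dimnames.
#' @export
read_connectome_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  w <- as.matrix(df)
  rownames(w) <- colnames(w)
  as_connectivity_matrix(w)
}
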