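#' Shortest-path distance matrix of a weighted network
#'
#' Edge lengths are the inverse weights (`d = 1/w`, the convention for
#' fiber-density connectomes: stronger connections are "closer"). Distances
#' are computed by Dijkstra's algorithm from every source node; unreachable
#' pairs get `Inf`, the diagonal is 0.
#'
#' @param w Connectivity matrix (non-negative, symmetric, zero diagonal).
#' @return Symmetric numeric matrix of pairwise shortest-path lengths.
#' @export
shortest_path_matrix <- function(w) {
  w <- as_connectivity_matrix(w)
  dijkstra_all_cpp(w)
}

#' Global network efficiency
#'
#' Mean over all ordered node pairs of the inverse shortest-path length,
#' with `1/Inf = 0`: the harmonic-mean style integration measure that stays
#' defined for disconnected networks. Scales linearly with the weights:
#' `E(s * w) = s * E(w)`.
#'
#' @param w Connectivity matrix, at least 2 nodes.
#' @param d Optional precomputed distance matrix from
#'   [shortest_path_matrix()] (avoids recomputation in loops).
#' @return Scalar efficiency, in units of weight.
#' @export
global_efficiency <- function(w, d = NULL) {
  if (is.null(d)) d <- shortest_path_matrix(w)
  n <- nrow(d)
  if (n < 2) stop("efficiency needs at least 2 nodes", call. = FALSE)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Characteristic path length
#'
#' Mean shortest-path length over reachable off-diagonal node pairs.
#' Unreachable pairs are excluded from the average; their count is attached
#' as attribute `n_unreachable` (ordered pairs). Scales as `L(s*w) = L(w)/s`.
#'
#' @inheritParams global_efficiency
#' @return Scalar path length (units 1/weight) with attribute
#'   `n_unreachable`.
#' @export
char_path_length <- function(w, d = NULL) {
  if (is.null(d)) d <- shortest_path_matrix(w)
  n <- nrow(d)
  if (n < 2) stop("path length needs at least 2 nodes", call. = FALSE)
  off <- d[row(d) != col(d)]
  finite <- off[is.finite(off)]
  if (length(finite) == 0) {
    stop("no finite path between any pair of nodes", call. = FALSE)
  }
  structure(mean(finite), n_unreachable = sum(!is.finite(off)))
}

#' Mean weighted clustering coefficient (Onnela)
#'
#' Per-node clustering is the geometric mean of triangle weights around the
#' node, weights first normalized by the largest weight in the network,
#' divided by the number of possible neighbour pairs `k(k-1)/2` (degrees are
#' binary). Nodes with degree < 2 contribute 0. The max-normalization makes
#' the measure invariant to uniform weight scaling.
#'
#' @param w Connectivity matrix.
#' @return Scalar in `[0, 1]`, the node average.
#' @export
clustering_coefficient <- function(w) {
  w <- as_connectivity_matrix(w)
  mx <- max(w)
  if (mx == 0) return(0)
  wn <- (w / mx)^(1 / 3)
  cyc3 <- diag(wn %*% wn %*% wn)  # 2 * sum of cube-root triangle weights
  k <- rowSums(w > 0)
  ci <- ifelse(k > 1, cyc3 / (k * (k - 1)), 0)
  mean(ci)
}

#' Modularity by Louvain optimisation with restarts
#'
#' Maximizes weighted Newman modularity with the Louvain algorithm. Because
#' Louvain is order-dependent, the optimisation is restarted `n_restarts`
#' times on randomly permuted vertex orders and the best partition kept
#' (first-found on ties). Randomness follows the current RNG state; pass
#' `seed` for a self-contained reproducible call.
#'
#' @param w Connectivity matrix with at least one edge.
#' @param n_restarts Number of seeded restarts (default 100).
#' @param seed Optional integer seed.
#' @return List with `Q` (best modularity) and `membership` (integer
#'   community labels).
#' @export
modularity_louvain <- function(w, n_restarts = 100, seed = NULL) {
  w <- as_connectivity_matrix(w)
  if (all(w == 0)) stop("modularity is undefined for an edgeless graph",
                        call. = FALSE)
  run <- function() {
    n <- nrow(w)
    best_q <- -Inf
    best_m <- NULL
    for (r in seq_len(n_restarts)) {
      perm <- sample.int(n)
      g <- igraph::graph_from_adjacency_matrix(
        w[perm, perm, drop = FALSE], mode = "undirected", weighted = TRUE)
      cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
      q <- igraph::modularity(cl)
      if (q > best_q + 1e-12) {
        best_q <- q
        m <- integer(n)
        m[perm] <- igraph::membership(cl)
        best_m <- m
      }
    }
    list(Q = best_q, membership = best_m)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Evaluate Newman modularity of a given partition
#'
#' Direct evaluation of the weighted modularity formula
#' `Q = sum_c (e_c/m - (d_c/2m)^2)`; used to check optimizer output and by
#' tests against exhaustive search.
#'
#' @param w Connectivity matrix.
#' @param membership Integer community labels, one per node.
#' @return Scalar modularity of that partition.
#' @export
modularity_value <- function(w, membership) {
  w <- as_connectivity_matrix(w)
  m2 <- sum(w)  # 2m
  if (m2 == 0) stop("modularity is undefined for an edgeless graph",
                    call. = FALSE)
  q <- 0
  for (cm in unique(membership)) {
    idx <- membership == cm
    e_c <- sum(w[idx, idx]) / m2
    d_c <- sum(w[idx, ]) / m2
    q <- q + e_c - d_c^2
  }
  q
}

#' Raw global network measures of one connectome
#'
#' Computes the four unnormalized global measures used in the analysis:
#' mean weighted clustering `C_raw`, modularity `Q`, characteristic path
#' length `L_raw`, and global efficiency `E`, together with edge count and
#' total strength.
#'
#' @param w Connectivity matrix.
#' @param n_restarts Louvain restarts for `Q`.
#' @param seed Optional seed for the modularity restarts.
#' @return One-row tibble with columns `C_raw`, `Q`, `L_raw`, `E`,
#'   `n_edges`, `total_strength`.
#' @export
network_metrics <- function(w, n_restarts = 100, seed = NULL) {
  w <- as_connectivity_matrix(w)
  d <- shortest_path_matrix(w)
  tibble::tibble(
    C_raw = clustering_coefficient(w),
    Q = modularity_louvain(w, n_restarts = n_restarts, seed = seed)$Q,
    L_raw = as.numeric(char_path_length(w, d = d)),
    E = global_efficiency(w, d = d),
    n_edges = n_edges(w),
    total_strength = total_strength(w)
  )
}
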