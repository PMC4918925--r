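# Independent brute-force oracles. These deliberately share no code with the
# package internals: Floyd-Warshall instead of Dijkstra, explicit triangle
# loops instead of matrix powers, exhaustive partition search instead of
# Louvain.

oracle_fw_dist <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  d[w > 0] <- 1 / w[w > 0]
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_efficiency <- function(w) {
  d <- oracle_fw_dist(w)
  n <- nrow(d)
  tot <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is.finite(d[i, j])) tot <- tot + 1 / d[i, j]
    }
  }
  tot / (n * (n - 1))
}

oracle_path_length <- function(w) {
  d <- oracle_fw_dist(w)
  vals <- c()
  n <- nrow(d)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is.finite(d[i, j])) vals <- c(vals, d[i, j])
    }
  }
  mean(vals)
}

# Onnela clustering by explicit neighbour-pair loops
oracle_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(0)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    tot <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        j <- nb[a]; h <- nb[b]
        if (w[j, h] > 0) {
          tot <- tot + ((w[i, j] / mx) * (w[i, h] / mx) *
                          (w[j, h] / mx))^(1 / 3)
        }
      }
    }
    ci[i] <- 2 * tot / (k * (k - 1))
  }
  mean(ci)
}

# all set partitions of 1..n (list of membership vectors)
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  smaller <- all_partitions(n - 1)
  out <- list()
  for (p in smaller) {
    for (cm in seq_len(max(p) + 1L)) {
      out[[length(out) + 1L]] <- c(p, cm)
    }
  }
  out
}

oracle_best_modularity <- function(w) {
  parts <- all_partitions(nrow(w))
  best <- -Inf
  for (p in parts) {
    q <- modularity_value(w, p)
    if (q > best) best <- q
  }
  best
}

# random connected-ish weighted graph for property loops
random_weighted_graph <- function(n, p_edge = 0.4, max_w = 1) {
  w <- matrix(0, n, n)
  up <- which(upper.tri(w))
  on <- runif(length(up)) < p_edge
  w[up[on]] <- runif(sum(on), 0.05, max_w)
  w <- w + t(w)
  # guarantee at least one edge
  if (all(w == 0)) {
    w[1, 2] <- w[2, 1] <- runif(1, 0.05, max_w)
  }
  w
}

# small calibration-friendly config for fast cohort tests
small_config <- function(...) {
  cohort_config(n_per_group = 4, n_nodes = 40, lattice_degree = 6,
                shortcut_prob_control = 0.3, shortcut_prob_patient = 0.1,
                ...)
}
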