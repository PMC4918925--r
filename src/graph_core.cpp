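#include <Rcpp.h>
#include <vector>
#include <limits>
#include <queue>
#include <cstdint>
using namespace Rcpp;

// All-pairs shortest paths on a weighted adjacency matrix, edge length 1/w.
// Dense O(V^2) Dijkstra per source: at connectome sizes (~150 nodes) this
// beats heap bookkeeping and avoids per-call graph construction overhead.
// [[Rcpp::export]]
NumericMatrix dijkstra_all_cpp(NumericMatrix W) {
  const int n = W.nrow();
  const double INF = std::numeric_limits<double>::infinity();
  NumericMatrix D(n, n);

  // adjacency lists of (neighbor, length)
  std::vector< std::vector<int> > nb(n);
  std::vector< std::vector<double> > len(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double w = W(i, j);
      if (i != j && w > 0.0) {
        nb[i].push_back(j);
        len[i].push_back(1.0 / w);
      }
    }
  }

  std::vector<double> dist(n);
  std::vector<char> done(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), INF);
    std::fill(done.begin(), done.end(), 0);
    dist[s] = 0.0;
    for (int it = 0; it < n; ++it) {
      int u = -1;
      double best = INF;
      for (int v = 0; v < n; ++v)
        if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
      if (u < 0) break;
      done[u] = 1;
      const std::vector<int>& nu = nb[u];
      const std::vector<double>& lu = len[u];
      for (size_t k = 0; k < nu.size(); ++k) {
        double alt = dist[u] + lu[k];
        if (alt < dist[nu[k]]) dist[nu[k]] = alt;
      }
    }
    for (int v = 0; v < n; ++v) D(s, v) = dist[v];
    D(s, s) = 0.0;
  }
  return D;
}

// Maslov-Sneppen degree-preserving rewiring; weights travel with edges.
// attempts = swaps_per_edge * n_edges random double-edge swaps; a swap is
// applied only if it keeps the graph simple. Uses R's RNG so results follow
// set.seed(). Returns the rewired matrix; attribute "n_swapped" counts
// applied swaps.
// [[Rcpp::export]]
NumericMatrix rewire_ms_cpp(NumericMatrix W, int swaps_per_edge) {
  const int n = W.nrow();
  NumericMatrix A(clone(W));
  std::vector<int> ei, ej;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (A(i, j) > 0.0) { ei.push_back(i); ej.push_back(j); }
  const int m = (int) ei.size();
  int n_swapped = 0;
  if (m >= 2) {
    const long attempts = (long) swaps_per_edge * m;
    for (long t = 0; t < attempts; ++t) {
      int e1 = (int) (unif_rand() * m);
      int e2 = (int) (unif_rand() * m);
      if (e1 == e2) continue;
      int a = ei[e1], b = ej[e1], c = ei[e2], d = ej[e2];
      if (unif_rand() < 0.5) std::swap(c, d);  // random orientation
      // proposed: (a,d) and (c,b)
      if (a == c || a == d || b == c || b == d) continue;
      if (A(a, d) > 0.0 || A(c, b) > 0.0) continue;
      double w1 = A(a, b), w2 = A(c, d);
      A(a, b) = A(b, a) = 0.0;
      A(c, d) = A(d, c) = 0.0;
      A(a, d) = A(d, a) = w1;
      A(c, b) = A(b, c) = w2;
      ei[e1] = a < d ? a : d; ej[e1] = a < d ? d : a;
      ei[e2] = c < b ? c : b; ej[e2] = c < b ? b : c;
      ++n_swapped;
    }
  }
  A.attr("n_swapped") = n_swapped;
  return A;
}

// ---- fast PRNG (xorshift128+), seeded from R's RNG so set.seed() governs
struct XS128 {
  uint64_t s0, s1;
  explicit XS128(uint64_t seed) {
    // splitmix64 expansion
    uint64_t z = seed;
    auto next = [&z]() {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      return t ^ (t >> 31);
    };
    s0 = next(); s1 = next();
    if (s0 == 0 && s1 == 0) s0 = 1;
  }
  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  // uniform in [0, n)
  int below(int n) { return (int)(next() % (uint64_t)n); }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

// mean finite off-diagonal shortest-path length (lengths 1/w), heap Dijkstra
static double char_path_csr(const std::vector<int>& head,
                            const std::vector<int>& adj,
                            const std::vector<double>& len, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist(n);
  typedef std::pair<double, int> QE;
  double total = 0.0;
  long n_finite = 0;
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), INF);
    dist[s] = 0.0;
    std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
    pq.push(QE(0.0, s));
    while (!pq.empty()) {
      QE top = pq.top(); pq.pop();
      if (top.first > dist[top.second]) continue;
      int u = top.second;
      for (int e = head[u]; e < head[u + 1]; ++e) {
        double alt = top.first + len[e];
        if (alt < dist[adj[e]]) {
          dist[adj[e]] = alt;
          pq.push(QE(alt, adj[e]));
        }
      }
    }
    for (int v = 0; v < n; ++v)
      if (v != s && dist[v] < INF) { total += dist[v]; ++n_finite; }
  }
  return n_finite > 0 ? total / n_finite : NA_REAL;
}

// Onnela mean weighted clustering; weights normalized by w_max (invariant
// under rewiring: the weight multiset is preserved)
static double onnela_clustering(const std::vector<double>& A, int n,
                                double wmax) {
  if (wmax <= 0) return 0.0;
  std::vector<double> A13(n * n, 0.0);
  std::vector< std::vector<int> > nbr(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (A[i * n + j] > 0) {
        A13[i * n + j] = std::cbrt(A[i * n + j] / wmax);
        nbr[i].push_back(j);
      }
  double csum = 0.0;
  for (int i = 0; i < n; ++i) {
    int k = (int) nbr[i].size();
    if (k < 2) continue;
    double t = 0.0;
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b) {
        int j = nbr[i][a], h = nbr[i][b];
        if (A13[j * n + h] > 0)
          t += A13[i * n + j] * A13[i * n + h] * A13[j * n + h];
      }
    csum += 2.0 * t / ((double) k * (k - 1));
  }
  return csum / n;
}

// Null-ensemble raw measures: for each of n_null Maslov-Sneppen rewires of
// W (fresh from the original each time, swaps_per_edge * n_edges attempts),
// the mean weighted clustering (Onnela) and/or characteristic path length.
// Columns: C_null, L_null (NA when not requested). Seeded from R's RNG.
// [[Rcpp::export]]
NumericMatrix null_metrics_cpp(NumericMatrix W, int n_null,
                               int swaps_per_edge, bool want_c,
                               bool want_l) {
  const int n = W.nrow();
  std::vector<int> e0i, e0j;
  std::vector<double> e0w;
  double wmax = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (W(i, j) > 0.0) {
        e0i.push_back(i); e0j.push_back(j); e0w.push_back(W(i, j));
        if (W(i, j) > wmax) wmax = W(i, j);
      }
  const int m = (int) e0i.size();
  NumericMatrix out(n_null, 2);
  std::fill(out.begin(), out.end(), NA_REAL);
  if (m < 2) return out;

  uint64_t seed = (uint64_t) (unif_rand() * 4294967296.0);
  seed = (seed << 32) ^ (uint64_t) (unif_rand() * 4294967296.0);
  XS128 rng(seed);

  std::vector<int> ei(m), ej(m);
  std::vector<double> ew(m);
  std::vector<double> A(n * n);
  std::vector<int> head(n + 1), deg(n), adj(2 * m);
  std::vector<double> len(2 * m);

  for (int b = 0; b < n_null; ++b) {
    ei = e0i; ej = e0j; ew = e0w;
    std::fill(A.begin(), A.end(), 0.0);
    for (int e = 0; e < m; ++e) {
      A[ei[e] * n + ej[e]] = ew[e];
      A[ej[e] * n + ei[e]] = ew[e];
    }
    long attempts = (long) swaps_per_edge * m;
    for (long t = 0; t < attempts; ++t) {
      int e1 = rng.below(m), e2 = rng.below(m);
      if (e1 == e2) continue;
      int a = ei[e1], bb = ej[e1], c = ei[e2], d = ej[e2];
      if (rng.next() & 1) std::swap(c, d);
      if (a == c || a == d || bb == c || bb == d) continue;
      if (A[a * n + d] > 0.0 || A[c * n + bb] > 0.0) continue;
      double w1 = A[a * n + bb], w2 = A[c * n + d];
      A[a * n + bb] = A[bb * n + a] = 0.0;
      A[c * n + d] = A[d * n + c] = 0.0;
      A[a * n + d] = A[d * n + a] = w1;
      A[c * n + bb] = A[bb * n + c] = w2;
      ei[e1] = a; ej[e1] = d;
      ei[e2] = c; ej[e2] = bb;
    }
    if (want_c) out(b, 0) = onnela_clustering(A, n, wmax);
    if (want_l) {
      std::fill(deg.begin(), deg.end(), 0);
      for (int e = 0; e < m; ++e) { ++deg[ei[e]]; ++deg[ej[e]]; }
      head[0] = 0;
      for (int v = 0; v < n; ++v) head[v + 1] = head[v] + deg[v];
      std::vector<int> pos(head.begin(), head.end() - 1);
      for (int e = 0; e < m; ++e) {
        double w = A[ei[e] * n + ej[e]];
        adj[pos[ei[e]]] = ej[e]; len[pos[ei[e]]++] = 1.0 / w;
        adj[pos[ej[e]]] = ei[e]; len[pos[ej[e]]++] = 1.0 / w;
      }
      out(b, 1) = char_path_csr(head, adj, len, n);
    }
  }
  return out;
}
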