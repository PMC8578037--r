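// Hot path of the density-sweep metric engine: Pearson association matrix,
// rank thresholding across the density grid, BFS-based global metrics
// (clustering, characteristic path length, global efficiency) and
// degree-preserving rewired references for the normalized small-world
// indices. Used for the global metrics inside permutation loops; modularity
// and nodal betweenness go through igraph in R.
//
// Randomness is drawn from R's RNG (set.seed on the R side governs the
// rewiring), so results are reproducible across the R/C++ boundary.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <queue>
using namespace Rcpp;

typedef std::vector<unsigned char> AdjMat;

static inline int at(int n, int i, int j) { return i * n + j; }

// BFS from every source; returns -1 for unreachable. dist is n*n ints.
static void bfs_all(const AdjMat& A, int n, std::vector<int>& dist,
                    const std::vector<std::vector<int> >& nbrs) {
  std::fill(dist.begin(), dist.end(), -1);
  std::vector<int> queue_buf(n);
  for (int s = 0; s < n; ++s) {
    int* d = &dist[s * (size_t)n];
    d[s] = 0;
    int head = 0, tail = 0;
    queue_buf[tail++] = s;
    while (head < tail) {
      int v = queue_buf[head++];
      const std::vector<int>& nb = nbrs[v];
      for (size_t k = 0; k < nb.size(); ++k) {
        int w = nb[k];
        if (d[w] < 0) { d[w] = d[v] + 1; queue_buf[tail++] = w; }
      }
    }
  }
}

struct GraphMetrics {
  double C, L, E;
  bool connected;
};

static GraphMetrics graph_metrics(const AdjMat& A, int n,
                                  const std::vector<std::vector<int> >& nbrs,
                                  bool want_dist) {
  GraphMetrics gm;
  // clustering: triangles via neighbor pairs
  double csum = 0.0;
  for (int v = 0; v < n; ++v) {
    const std::vector<int>& nb = nbrs[v];
    int k = (int)nb.size();
    if (k < 2) continue;
    int links = 0;
    for (int a = 0; a < k - 1; ++a)
      for (int b = a + 1; b < k; ++b)
        links += A[at(n, nb[a], nb[b])];
    csum += (double)links / (k * (k - 1) / 2.0);
  }
  gm.C = csum / n;
  gm.L = NA_REAL;
  gm.E = NA_REAL;
  gm.connected = true;
  if (!want_dist) return gm;
  std::vector<int> dist((size_t)n * n);
  bfs_all(A, n, dist, nbrs);
  double lsum = 0.0, esum = 0.0;
  long cnt = 0;
  bool conn = true;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      int d = dist[at(n, i, j)];
      ++cnt;
      if (d < 0) { conn = false; continue; }
      lsum += d;
      esum += 1.0 / d;
    }
  gm.connected = conn;
  gm.L = conn ? lsum / cnt : NA_REAL;
  gm.E = esum / cnt;
  return gm;
}

static std::vector<std::vector<int> > neighbor_lists(const AdjMat& A, int n) {
  std::vector<std::vector<int> > nbrs(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (A[at(n, i, j)]) nbrs[i].push_back(j);
  return nbrs;
}

// Degree-preserving double-edge swaps on a copy of the graph. n_swaps
// attempted swaps; invalid proposals (self-loop, multi-edge, same edge)
// are skipped. Edges kept as parallel vectors.
static void rewire(AdjMat& A, int n, std::vector<int>& eu,
                   std::vector<int>& ev, int n_swaps) {
  int m = (int)eu.size();
  if (m < 2) return;
  for (int it = 0; it < n_swaps; ++it) {
    int e1 = (int)(unif_rand() * m);
    int e2 = (int)(unif_rand() * m);
    if (e1 == e2) continue;
    int a = eu[e1], b = ev[e1], c = eu[e2], d = ev[e2];
    if (unif_rand() < 0.5) std::swap(c, d);
    // propose (a,d) and (c,b)
    if (a == d || c == b) continue;
    if (a == c || b == d) continue;
    if (A[at(n, a, d)] || A[at(n, c, b)]) continue;
    A[at(n, a, b)] = A[at(n, b, a)] = 0;
    A[at(n, c, d)] = A[at(n, d, c)] = 0;
    A[at(n, a, d)] = A[at(n, d, a)] = 1;
    A[at(n, c, b)] = A[at(n, b, c)] = 1;
    eu[e1] = a; ev[e1] = d;
    eu[e2] = c; ev[e2] = b;   // c may be the swapped orientation
  }
}

static bool is_connected(const AdjMat& A, int n) {
  std::vector<std::vector<int> > nbrs = neighbor_lists(A, n);
  std::vector<int> seen(n, 0);
  std::vector<int> stack;
  stack.push_back(0);
  seen[0] = 1;
  int cnt = 1;
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    for (size_t k = 0; k < nbrs[v].size(); ++k) {
      int w = nbrs[v][k];
      if (!seen[w]) { seen[w] = 1; ++cnt; stack.push_back(w); }
    }
  }
  return cnt == n;
}

// [[Rcpp::export(name = ".cpp_sweep_global")]]
List cpp_sweep_global(NumericMatrix R_assoc, NumericVector densities,
                      bool want_L, bool want_E, bool want_sw,
                      int n_random, int rewire_mult, int max_retries) {
  int n = R_assoc.nrow();
  int n_pairs = n * (n - 1) / 2;
  int nd = densities.size();

  // rank pairs by decreasing r, ties by lexicographic (i, j)
  std::vector<int> pi(n_pairs), pj(n_pairs), ord(n_pairs);
  std::vector<double> pr(n_pairs);
  {
    int idx = 0;
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) {
        pi[idx] = i; pj[idx] = j; pr[idx] = R_assoc(i, j); ++idx;
      }
    for (int k = 0; k < n_pairs; ++k) ord[k] = k;
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return pr[a] > pr[b]; });
  }

  AdjMat A((size_t)n * n, 0);
  NumericMatrix out(7, nd); // rows: C, L, E, gamma, lambda, sigma, density
  LogicalVector connected(nd);
  std::fill(out.begin(), out.end(), NA_REAL);

  int k_prev = 0;
  std::vector<int> eu, ev;
  eu.reserve(n_pairs); ev.reserve(n_pairs);
  bool want_dist = want_L || want_E || want_sw;

  for (int d = 0; d < nd; ++d) {
    int k = (int)std::floor(densities[d] * n_pairs + 1e-9);
    if (k < 1) stop("density too low: target edge count is 0");
    for (int t = k_prev; t < k; ++t) {
      int i = pi[ord[t]], j = pj[ord[t]];
      A[at(n, i, j)] = A[at(n, j, i)] = 1;
      eu.push_back(i); ev.push_back(j);
    }
    k_prev = k;
    std::vector<std::vector<int> > nbrs = neighbor_lists(A, n);
    GraphMetrics gm = graph_metrics(A, n, nbrs, want_dist);
    connected[d] = gm.connected;
    out(0, d) = gm.C;
    if (want_L) out(1, d) = gm.L;
    if (want_E) out(2, d) = gm.E;
    out(6, d) = (double)k / n_pairs;

    if (want_sw && gm.connected) {
      double cr_sum = 0.0, lr_sum = 0.0;
      int got = 0;
      int m = (int)eu.size();
      for (int r = 0; r < n_random; ++r) {
        for (int attempt = 0; attempt < max_retries; ++attempt) {
          AdjMat A2(A);
          std::vector<int> eu2(eu), ev2(ev);
          rewire(A2, n, eu2, ev2, rewire_mult * m);
          if (!is_connected(A2, n)) continue;
          std::vector<std::vector<int> > nb2 = neighbor_lists(A2, n);
          GraphMetrics g2 = graph_metrics(A2, n, nb2, true);
          cr_sum += g2.C;
          lr_sum += g2.L;
          ++got;
          break;
        }
      }
      if (got > 0 && cr_sum > 0) {
        double gamma = gm.C / (cr_sum / got);
        double lambda = gm.L / (lr_sum / got);
        out(3, d) = gamma;
        out(4, d) = lambda;
        out(5, d) = gamma / lambda;
      }
    }
  }
  rownames(out) = CharacterVector::create("C", "L", "E_global", "gamma",
                                          "lambda", "sigma", "density");
  return List::create(_["global"] = out, _["connected"] = connected);
}
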