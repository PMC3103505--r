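#include <Rcpp.h>
#include <vector>
#include <queue>
#include <utility>
#include <cmath>
using namespace Rcpp;

// Null-ensemble statistics for the small-world ratios.
//
// Each ensemble member starts from the observed edge list, applies
// `n_swaps` degree-preserving double-edge swap attempts
// ((a,b),(c,d) -> (a,d),(c,b), rejected when endpoints coincide or the
// target edges exist), and shuffles the weight multiset onto the
// surviving edges. Disconnected draws are resampled (up to `max_retries`
// attempts). For every draw the mean Onnela clustering coefficient is
// recorded (weights scaled by the network maximum when `scaled`); for the
// first `ens_L` draws the characteristic path length with arc lengths
// 1/w is recorded as well (all-pairs Dijkstra). All randomness comes from
// R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List null_ensemble_stats(IntegerMatrix edges, NumericVector weights,
                         int n, IntegerVector kdeg, int ens_C, int ens_L,
                         int n_swaps, bool scaled, int max_retries) {
  const int m = edges.nrow();
  const int draws = std::max(ens_C, ens_L);
  NumericVector C_rand(ens_C), L_rand(ens_L);
  double wmax = 0.0;
  for (int e = 0; e < m; e++) wmax = std::max(wmax, weights[e]);
  std::vector<double> a0(m), w0(m);
  for (int e = 0; e < m; e++) {
    w0[e] = weights[e];
    a0[e] = std::cbrt(scaled ? weights[e] / wmax : weights[e]);
  }

  std::vector<int> ei0(m), ej0(m);
  for (int e = 0; e < m; e++) {
    ei0[e] = edges(e, 0) - 1;
    ej0[e] = edges(e, 1) - 1;
  }

  std::vector<signed char> adj((size_t)n * n);
  std::vector<double> aw((size_t)n * n);
  std::vector<int> ei(m), ej(m), perm(m);
  std::vector<std::vector<std::pair<int, double> > > nbw(n);
  std::vector<std::vector<int> > nb(n);
  std::vector<int> queue_(n), seen(n);
  std::vector<double> dist(n);

  for (int s = 0; s < draws; s++) {
    bool ok = false;
    for (int r = 0; r < max_retries && !ok; r++) {
      ei = ei0;
      ej = ej0;
      std::fill(adj.begin(), adj.end(), 0);
      for (int e = 0; e < m; e++) {
        adj[(size_t)ei[e] * n + ej[e]] = 1;
        adj[(size_t)ej[e] * n + ei[e]] = 1;
      }
      for (int t = 0; t < n_swaps; t++) {
        int e1 = (int)(unif_rand() * m);
        int e2 = (int)(unif_rand() * m);
        if (e1 >= m) e1 = m - 1;
        if (e2 >= m) e2 = m - 1;
        if (e1 == e2) continue;
        int a = ei[e1], b = ej[e1], c = ei[e2], d = ej[e2];
        if (a == c || a == d || b == c || b == d) continue;
        if (adj[(size_t)a * n + d] || adj[(size_t)c * n + b]) continue;
        adj[(size_t)a * n + b] = adj[(size_t)b * n + a] = 0;
        adj[(size_t)c * n + d] = adj[(size_t)d * n + c] = 0;
        adj[(size_t)a * n + d] = adj[(size_t)d * n + a] = 1;
        adj[(size_t)c * n + b] = adj[(size_t)b * n + c] = 1;
        ej[e1] = d;
        ej[e2] = b;
      }
      // shuffled weight multiset (Fisher-Yates permutation of edge slots)
      for (int e = 0; e < m; e++) perm[e] = e;
      for (int e = m - 1; e > 0; e--) {
        int j = (int)(unif_rand() * (e + 1));
        if (j > e) j = e;
        std::swap(perm[e], perm[j]);
      }
      for (int i = 0; i < n; i++) {
        nb[i].clear();
        nbw[i].clear();
      }
      std::fill(aw.begin(), aw.end(), 0.0);
      for (int e = 0; e < m; e++) {
        double a3 = a0[perm[e]];
        double len = 1.0 / w0[perm[e]];
        aw[(size_t)ei[e] * n + ej[e]] = a3;
        aw[(size_t)ej[e] * n + ei[e]] = a3;
        nb[ei[e]].push_back(ej[e]);
        nb[ej[e]].push_back(ei[e]);
        nbw[ei[e]].push_back(std::make_pair(ej[e], len));
        nbw[ej[e]].push_back(std::make_pair(ei[e], len));
      }
      // connectivity (BFS from node 0)
      std::fill(seen.begin(), seen.end(), 0);
      int head = 0, tail = 0, reached = 1;
      queue_[tail++] = 0;
      seen[0] = 1;
      while (head < tail) {
        int v = queue_[head++];
        for (size_t q = 0; q < nb[v].size(); q++) {
          int u = nb[v][q];
          if (!seen[u]) {
            seen[u] = 1;
            reached++;
            queue_[tail++] = u;
          }
        }
      }
      if (reached < n) continue;

      if (s < ens_C) {
        // mean Onnela clustering: per node, sum over unordered neighbor
        // pairs of (a_ij a_ih a_jh), doubled for ordered pairs
        double total = 0.0;
        for (int i = 0; i < n; i++) {
          int k = kdeg[i];
          if (k < 2) continue;
          const std::vector<int> &ni = nb[i];
          double num = 0.0;
          for (size_t p = 0; p < ni.size(); p++) {
            for (size_t q = p + 1; q < ni.size(); q++) {
              double ajh = aw[(size_t)ni[p] * n + ni[q]];
              if (ajh > 0.0)
                num += aw[(size_t)i * n + ni[p]] *
                       aw[(size_t)i * n + ni[q]] * ajh;
            }
          }
          total += 2.0 * num / ((double)k * (k - 1));
        }
        C_rand[s] = total / n;
      }

      if (s < ens_L) {
        // all-pairs Dijkstra (lazy-deletion binary heap), arc length 1/w
        double sum_d = 0.0;
        for (int src = 0; src < n; src++) {
          std::fill(dist.begin(), dist.end(), R_PosInf);
          dist[src] = 0.0;
          std::priority_queue<std::pair<double, int>,
                              std::vector<std::pair<double, int> >,
                              std::greater<std::pair<double, int> > > pq;
          pq.push(std::make_pair(0.0, src));
          while (!pq.empty()) {
            std::pair<double, int> top = pq.top();
            pq.pop();
            if (top.first > dist[top.second]) continue;
            int v = top.second;
            for (size_t q = 0; q < nbw[v].size(); q++) {
              double nd = top.first + nbw[v][q].second;
              int u = nbw[v][q].first;
              if (nd < dist[u]) {
                dist[u] = nd;
                pq.push(std::make_pair(nd, u));
              }
            }
          }
          for (int v = 0; v < n; v++)
            if (v != src) sum_d += dist[v];
        }
        L_rand[s] = sum_d / ((double)n * (n - 1));
      }
      ok = true;
    }
    if (!ok) stop("Could not draw a connected null network; increase `max_retries`.");
  }
  return List::create(Named("C_rand") = C_rand, Named("L_rand") = L_rand);
}
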