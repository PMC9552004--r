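// Graph-theory kernels for 19-node brain networks.
//
// Per-epoch, per-band normalization against 100 degree-preserving random
// networks makes these the innermost loop of feature extraction, hence C++.
// All randomness goes through R's RNG (unif_rand) so results are
// reproducible under set.seed() from R.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Mean shortest-path length (characteristic path length) with edge length
// 1/weight, Floyd-Warshall. Returns +Inf if the graph is disconnected.
// [[Rcpp::export]]
double cpp_pathlength(NumericMatrix W) {
  int n = W.nrow();
  std::vector<double> D(n * n);
  const double INF = std::numeric_limits<double>::infinity();
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      D[i * n + j] = (i == j) ? 0.0 : (W(i, j) > 0 ? 1.0 / W(i, j) : INF);
  for (int k = 0; k < n; ++k)
    for (int i = 0; i < n; ++i) {
      double dik = D[i * n + k];
      if (dik == INF) continue;
      for (int j = 0; j < n; ++j) {
        double alt = dik + D[k * n + j];
        if (alt < D[i * n + j]) D[i * n + j] = alt;
      }
    }
  double s = 0.0;
  int cnt = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j) {
        if (D[i * n + j] == INF) return INF;
        s += D[i * n + j];
        ++cnt;
      }
  return s / cnt;
}

// Mean weighted clustering coefficient (Onnela: geometric mean of triangle
// weights, weights scaled by the maximum). Reduces to the binary clustering
// coefficient on 0/1 matrices. Nodes with degree < 2 contribute 0.
// [[Rcpp::export]]
double cpp_clustering(NumericMatrix W) {
  int n = W.nrow();
  double wmax = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && W(i, j) > wmax) wmax = W(i, j);
  if (wmax <= 0) return 0.0;
  std::vector<double> w3(n * n);
  std::vector<int> deg(n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double w = (i == j) ? 0.0 : W(i, j) / wmax;
      w3[i * n + j] = std::cbrt(w);
      if (i != j && W(i, j) > 0) deg[i]++;
    }
  double csum = 0.0;
  for (int i = 0; i < n; ++i) {
    if (deg[i] < 2) continue;
    double t = 0.0;
    for (int j = 0; j < n; ++j) {
      if (w3[i * n + j] == 0) continue;
      for (int k = 0; k < n; ++k) {
        if (k == i || k == j) continue;
        t += w3[i * n + j] * w3[j * n + k] * w3[k * n + i];
      }
    }
    csum += t / (deg[i] * (deg[i] - 1.0));
  }
  return csum / n;
}

static double modularity_of(const std::vector<double>& A, int n,
                            const std::vector<int>& memb, double two_m) {
  // Q = (1/2m) sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j)
  std::vector<double> k(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) k[i] += A[i * n + j];
  double q = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (memb[i] == memb[j]) q += A[i * n + j] - k[i] * k[j] / two_m;
  return q / two_m;
}

// One full Louvain run (local moving + aggregation) on a symmetric
// non-negative matrix; returns the membership on the original nodes.
static void louvain_once(const std::vector<double>& A0, int n0,
                         std::vector<int>& memb_out) {
  std::vector<double> A = A0;
  int n = n0;
  std::vector<int> global(n0);
  for (int i = 0; i < n0; ++i) global[i] = i;

  double two_m = 0.0;
  for (double v : A) two_m += v;
  if (two_m <= 0) {
    memb_out.assign(n0, 0);
    for (int i = 0; i < n0; ++i) memb_out[i] = i;
    return;
  }

  bool improved_any = true;
  while (improved_any) {
    improved_any = false;
    std::vector<int> comm(n);
    for (int i = 0; i < n; ++i) comm[i] = i;
    std::vector<double> k(n, 0.0), sigma(n, 0.0);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j) k[i] += A[i * n + j];
      sigma[i] = k[i];
    }
    // random node order via R RNG
    std::vector<int> order(n);
    for (int i = 0; i < n; ++i) order[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    bool moved = true;
    while (moved) {
      moved = false;
      for (int oi = 0; oi < n; ++oi) {
        int u = order[oi];
        int cu = comm[u];
        std::vector<double> wto(n, 0.0);
        for (int v = 0; v < n; ++v)
          if (v != u && A[u * n + v] > 0) wto[comm[v]] += A[u * n + v];
        double sig_cu = sigma[cu] - k[u];
        double best_gain = wto[cu] - k[u] * sig_cu / two_m;
        int best_c = cu;
        for (int c = 0; c < n; ++c) {
          if (c == cu || wto[c] == 0) continue;
          double gain = wto[c] - k[u] * sigma[c] / two_m;
          if (gain > best_gain + 1e-12 ||
              (std::abs(gain - best_gain) <= 1e-12 && c < best_c)) {
            best_gain = gain;
            best_c = c;
          }
        }
        if (best_c != cu) {
          sigma[cu] -= k[u];
          sigma[best_c] += k[u];
          comm[u] = best_c;
          moved = true;
          improved_any = true;
        }
      }
    }
    // relabel communities consecutively
    std::vector<int> relabel(n, -1);
    int nc = 0;
    for (int i = 0; i < n; ++i)
      if (relabel[comm[i]] < 0) relabel[comm[i]] = nc++;
    for (int i = 0; i < n; ++i) comm[i] = relabel[comm[i]];
    for (int i = 0; i < n0; ++i) global[i] = comm[global[i]];
    if (nc == n) break;
    // aggregate: B = P' A P
    std::vector<double> B(nc * nc, 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        B[comm[i] * nc + comm[j]] += A[i * n + j];
    A = B;
    n = nc;
  }
  memb_out = global;
}

// Best-of-`restarts` Louvain modularity. Uses R's RNG.
// [[Rcpp::export]]
List cpp_louvain(NumericMatrix W, int restarts = 10) {
  int n = W.nrow();
  std::vector<double> A(n * n);
  double two_m = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      A[i * n + j] = (i == j) ? 0.0 : W(i, j);
      two_m += A[i * n + j];
    }
  if (two_m <= 0) {
    IntegerVector m0(n);
    for (int i = 0; i < n; ++i) m0[i] = i + 1;
    return List::create(_["modularity"] = 0.0, _["membership"] = m0);
  }
  double best_q = -2.0;
  std::vector<int> best_m;
  for (int r = 0; r < restarts; ++r) {
    std::vector<int> memb;
    louvain_once(A, n, memb);
    double q = modularity_of(A, n, memb, two_m);
    if (q > best_q) {
      best_q = q;
      best_m = memb;
    }
  }
  IntegerVector mv(n);
  for (int i = 0; i < n; ++i) mv[i] = best_m[i] + 1;
  return List::create(_["modularity"] = best_q, _["membership"] = mv);
}

// Degree-preserving rewiring by double-edge swaps (Maslov-Sneppen).
// `attempts` swap attempts; unsuccessful attempts are skipped.
// [[Rcpp::export]]
NumericMatrix cpp_rewire(NumericMatrix A, int attempts) {
  int n = A.nrow();
  NumericMatrix B(clone(A));
  std::vector<int> ei, ej;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (B(i, j) > 0) {
        ei.push_back(i);
        ej.push_back(j);
      }
  int ne = ei.size();
  if (ne < 2) return B;
  for (int t = 0; t < attempts; ++t) {
    int a = (int)std::floor(unif_rand() * ne);
    int b = (int)std::floor(unif_rand() * ne);
    if (a >= ne) a = ne - 1;
    if (b >= ne) b = ne - 1;
    if (a == b) continue;
    int u = ei[a], v = ej[a], x = ei[b], y = ej[b];
    if (unif_rand() < 0.5) std::swap(x, y);
    // propose (u,v),(x,y) -> (u,x),(v,y)
    if (u == x || u == y || v == x || v == y) continue;
    if (B(u, x) > 0 || B(v, y) > 0) continue;
    double w1 = B(u, v), w2 = B(x, y);
    B(u, v) = B(v, u) = 0;
    B(x, y) = B(y, x) = 0;
    B(u, x) = B(x, u) = w1;
    B(v, y) = B(y, v) = w2;
    ei[a] = std::min(u, x); ej[a] = std::max(u, x);
    ei[b] = std::min(v, y); ej[b] = std::max(v, y);
  }
  return B;
}

// Metrics of one graph: path length, clustering, modularity, mean strength.
// [[Rcpp::export]]
NumericVector cpp_graph_metrics(NumericMatrix W, int restarts = 10) {
  int n = W.nrow();
  double strength = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j) strength += W(i, j);
  strength /= n;
  List lv = cpp_louvain(W, restarts);
  NumericVector out = NumericVector::create(
    _["pathlen"] = cpp_pathlength(W),
    _["clust"] = cpp_clustering(W),
    _["modularity"] = as<double>(lv["modularity"]),
    _["strength"] = strength);
  return out;
}

// Metrics over an ensemble of degree-preserving surrogates of W.
// weighted = true additionally permutes the edge weights over the rewired
// topology (preserving the degree sequence exactly and the strength
// distribution approximately); weighted = false expects a 0/1 matrix.
// Returns an n_surr x 4 matrix (pathlen, clust, modularity, strength).
// [[Rcpp::export]]
NumericMatrix cpp_ensemble_metrics(NumericMatrix W, int n_surr, bool weighted,
                                   int restarts = 2, int swap_factor = 10) {
  int n = W.nrow();
  std::vector<double> wts;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (W(i, j) > 0) wts.push_back(W(i, j));
  int ne = wts.size();
  NumericMatrix out(n_surr, 4);
  for (int s = 0; s < n_surr; ++s) {
    NumericMatrix R = cpp_rewire(W, swap_factor * ne);
    if (weighted && ne > 1) {
      // permute original weights over the rewired edge set
      std::vector<double> perm = wts;
      for (int i = ne - 1; i > 0; --i) {
        int j = (int)std::floor(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(perm[i], perm[j]);
      }
      int idx = 0;
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j)
          if (R(i, j) > 0) {
            R(i, j) = R(j, i) = perm[idx++];
          }
    }
    NumericVector m = cpp_graph_metrics(R, restarts);
    for (int k = 0; k < 4; ++k) out(s, k) = m[k];
  }
  colnames(out) = CharacterVector::create("pathlen", "clust", "modularity",
                                          "strength");
  return out;
}

// Weighted and directed phase-lag indices from the real/imaginary parts of
// the analytic signals (channels x samples). One pass over the imaginary
// cross-terms per channel pair.
// [[Rcpp::export(rng = false)]]
List cpp_phase_lag(NumericMatrix X, NumericMatrix Y) {
  int nch = X.nrow(), n = X.ncol();
  // contiguous per-channel copies: the R matrices are channel-major
  std::vector< std::vector<double> > xr(nch), yr(nch);
  for (int i = 0; i < nch; ++i) {
    xr[i].resize(n);
    yr[i].resize(n);
    for (int t = 0; t < n; ++t) {
      xr[i][t] = X(i, t);
      yr[i][t] = Y(i, t);
    }
  }
  NumericMatrix W(nch, nch), D(nch, nch);
  for (int i = 0; i < nch; ++i) D(i, i) = 0.5;
  for (int i = 0; i < nch - 1; ++i) {
    const double* xi = xr[i].data();
    const double* yi = yr[i].data();
    for (int j = i + 1; j < nch; ++j) {
      const double* xj = xr[j].data();
      const double* yj = yr[j].data();
      double s = 0, sa = 0, pos = 0, zero = 0;
      for (int t = 0; t < n; ++t) {
        double im = yi[t] * xj[t] - xi[t] * yj[t];
        s += im;
        sa += std::fabs(im);
        if (im > 0) pos += 1;
        else if (im == 0) zero += 1;
      }
      double w = (sa == 0) ? 0.0 : std::fabs(s) / sa;
      double d = (pos + 0.5 * zero) / n;
      W(i, j) = W(j, i) = w;
      D(i, j) = d;
      D(j, i) = 1 - d;
    }
  }
  return List::create(_["wpli"] = W, _["dpli"] = D);
}
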