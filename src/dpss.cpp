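// Discrete prolate spheroidal (Slepian) tapers.
//
// Uses the classical tridiagonal formulation: the tapers are eigenvectors of
// a symmetric tridiagonal matrix that commutes with the time-bandwidth
// concentration operator. The top-K eigenvalues are located by bisection on
// Sturm-sequence counts and the eigenvectors recovered by inverse iteration
// with a partial-pivoting tridiagonal solver.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// number of eigenvalues of the tridiagonal (d, e) strictly less than x
static int sturm_count(const std::vector<double>& d,
                       const std::vector<double>& e, double x) {
  int n = d.size();
  int count = 0;
  double q = d[0] - x;
  if (q < 0) ++count;
  for (int i = 1; i < n; ++i) {
    if (q == 0) q = 1e-300;
    q = d[i] - x - e[i] * e[i] / q;
    if (q < 0) ++count;
  }
  return count;
}

// solve (T - lambda I) y = b for tridiagonal T, partial pivoting
static void tri_solve(const std::vector<double>& d,
                      const std::vector<double>& e, double lambda,
                      std::vector<double>& b) {
  int n = d.size();
  std::vector<double> dl(n), dd(n), du(n), du2(n, 0.0);
  for (int i = 0; i < n; ++i) {
    dd[i] = d[i] - lambda;
    dl[i] = (i > 0) ? e[i] : 0.0;      // sub-diagonal entering row i
    du[i] = (i < n - 1) ? e[i + 1] : 0.0;
  }
  std::vector<int> piv(n, 0);
  for (int i = 0; i < n - 1; ++i) {
    if (std::fabs(dl[i + 1]) > std::fabs(dd[i])) {
      // swap row i and i+1
      std::swap(dd[i], dl[i + 1]);
      std::swap(du[i], dd[i + 1]);
      if (i < n - 2) { du2[i] = du[i + 1]; du[i + 1] = 0.0; }
      std::swap(b[i], b[i + 1]);
      piv[i] = 1;
    }
    if (dd[i] == 0) dd[i] = 1e-300;
    double m = dl[i + 1] / dd[i];
    dd[i + 1] -= m * du[i];
    if (i < n - 2) du[i + 1] -= m * du2[i];
    b[i + 1] -= m * b[i];
  }
  if (dd[n - 1] == 0) dd[n - 1] = 1e-300;
  b[n - 1] /= dd[n - 1];
  if (n > 1) b[n - 2] = (b[n - 2] - du[n - 2] * b[n - 1]) / dd[n - 2];
  for (int i = n - 3; i >= 0; --i)
    b[i] = (b[i] - du[i] * b[i + 1] - du2[i] * b[i + 2]) / dd[i];
}

// [[Rcpp::export(rng = false)]]
NumericMatrix cpp_dpss(int n, double nw, int k) {
  if (k < 1 || n < 2) stop("invalid dpss request");
  if (k > 2 * nw - 1 + 1e-9) stop("Slepian constraint K <= 2*NW - 1 violated");
  double W = nw / n;
  double ctw = std::cos(2 * M_PI * W);
  std::vector<double> d(n), e(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double h = (n - 1 - 2.0 * i) / 2.0;
    d[i] = h * h * ctw;
  }
  for (int i = 1; i < n; ++i) e[i] = i * (n - i) / 2.0;

  // Gershgorin bounds
  double lo = d[0], hi = d[0];
  for (int i = 0; i < n; ++i) {
    double r = ((i > 0) ? std::fabs(e[i]) : 0.0) +
               ((i < n - 1) ? std::fabs(e[i + 1]) : 0.0);
    lo = std::min(lo, d[i] - r);
    hi = std::max(hi, d[i] + r);
  }

  NumericMatrix tapers(n, k);
  std::vector<std::vector<double> > found;
  for (int j = 0; j < k; ++j) {
    int idx = n - 1 - j;  // ascending index of the j-th largest eigenvalue
    double a = lo, b = hi;
    for (int it = 0; it < 100; ++it) {
      double mid = 0.5 * (a + b);
      if (sturm_count(d, e, mid) <= idx) a = mid; else b = mid;
    }
    double lambda = 0.5 * (a + b);
    // inverse iteration
    std::vector<double> v(n);
    for (int i = 0; i < n; ++i)
      v[i] = std::sin((j + 1) * M_PI * (i + 1.0) / (n + 1.0));
    for (int it = 0; it < 4; ++it) {
      tri_solve(d, e, lambda, v);
      for (size_t f = 0; f < found.size(); ++f) {
        double dot = 0;
        for (int i = 0; i < n; ++i) dot += v[i] * found[f][i];
        for (int i = 0; i < n; ++i) v[i] -= dot * found[f][i];
      }
      double nrm = 0;
      for (int i = 0; i < n; ++i) nrm += v[i] * v[i];
      nrm = std::sqrt(nrm);
      if (nrm == 0) stop("inverse iteration failed");
      for (int i = 0; i < n; ++i) v[i] /= nrm;
    }
    // sign convention: symmetric tapers have positive mean; antisymmetric
    // tapers start positive
    double sum = 0, amax = 0;
    for (int i = 0; i < n; ++i) {
      sum += v[i];
      amax = std::max(amax, std::fabs(v[i]));
    }
    bool flip;
    if (std::fabs(sum) > 1e-7 * n * amax) {
      flip = sum < 0;
    } else {
      int i0 = 0;
      while (i0 < n - 1 && std::fabs(v[i0]) < 1e-7 * amax) ++i0;
      flip = v[i0] < 0;
    }
    if (flip) for (int i = 0; i < n; ++i) v[i] = -v[i];
    for (int i = 0; i < n; ++i) tapers(i, j) = v[i];
    found.push_back(v);
  }
  return tapers;
}
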