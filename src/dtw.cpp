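#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Classic dynamic time warping with absolute-difference local cost and the
// unit step pattern (diagonal / horizontal / vertical), optionally limited
// to a Sakoe-Chiba band of half-width `band` (band < 0 disables it).
// Rolling two-row DP keeps memory at O(min series length).
static double dtw_pair(const double* a, int n, const double* b, int m,
                       int band) {
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> prev(m + 1, inf), cur(m + 1, inf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    int jlo = 1, jhi = m;
    if (band >= 0) {
      // band defined on indices scaled to the longer axis
      double slope = (double)m / n;
      int c = (int)std::lround(i * slope);
      jlo = std::max(1, c - band);
      jhi = std::min(m, c + band);
      std::fill(cur.begin(), cur.end(), inf);
    }
    cur[jlo - 1] = inf;
    const double ai = a[i - 1];
    double diag = prev[jlo - 1];  // prev[j-1] carried across iterations
    double left = inf;            // cur[j-1]
    for (int j = jlo; j <= jhi; ++j) {
      double up = prev[j];
      double best = diag < up ? diag : up;
      if (left < best) best = left;
      left = std::fabs(ai - b[j - 1]) + best;
      cur[j] = left;
      diag = up;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export(name = ".dtw_cost")]]
double dtw_cost(NumericVector a, NumericVector b, int band = -1) {
  if (a.size() == 0 || b.size() == 0)
    stop("dtw: series must be non-empty");
  return dtw_pair(a.begin(), a.size(), b.begin(), b.size(), band);
}

// [[Rcpp::export(name = ".dtw_cost_matrix")]]
NumericMatrix dtw_cost_matrix(List series, int band = -1) {
  int n = series.size();
  std::vector<NumericVector> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<NumericVector>(series[i]);
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double v = dtw_pair(s[i].begin(), s[i].size(),
                          s[j].begin(), s[j].size(), band);
      d(i, j) = v;
      d(j, i) = v;
    }
  }
  return d;
}
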