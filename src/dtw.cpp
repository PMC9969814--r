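#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// Dynamic-programming DTW cost between two sequences.
// Local cost |x_i - y_j|; symmetric unit-weight steps
// {diagonal, up, right}; boundary-to-boundary path.
// `window`: optional Sakoe-Chiba band half-width in samples on the
// slope-corrected index difference; < 0 disables the constraint.
static double dtw_core(const double* x, const int n, const double* y,
                       const int m, const int window) {
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> prev(m, inf), cur(m, inf);
  const double slope = (n > 1) ? (double)(m - 1) / (double)(n - 1) : 0.0;

  prev[0] = std::fabs(x[0] - y[0]);
  for (int j = 1; j < m; ++j) {
    if (window >= 0 && j > window) break;
    prev[j] = prev[j - 1] + std::fabs(x[0] - y[j]);
  }
  if (window < 0) {
    // unconstrained path: keep the left neighbour and the diagonal in
    // registers so the dependent min-chain is as short as possible
    for (int i = 1; i < n; ++i) {
      const double xi = x[i];
      double diag = prev[0];
      double left = diag + std::fabs(xi - y[0]);
      cur[0] = left;
      for (int j = 1; j < m; ++j) {
        const double up = prev[j];
        double best = diag < up ? diag : up;
        if (left < best) best = left;
        left = std::fabs(xi - y[j]) + best;
        cur[j] = left;
        diag = up;
      }
      std::swap(prev, cur);
    }
    return prev[m - 1];
  }
  for (int i = 1; i < n; ++i) {
    const double c = slope * i;
    const int jlo = std::max(0, (int)std::ceil(c - window));
    const int jhi = std::min(m - 1, (int)std::floor(c + window));
    std::fill(cur.begin(), cur.end(), inf);
    for (int j = jlo; j <= jhi; ++j) {
      const double cost = std::fabs(x[i] - y[j]);
      double best = prev[j];                               // up
      if (j > 0) {
        if (prev[j - 1] < best) best = prev[j - 1];        // diagonal
        if (cur[j - 1] < best) best = cur[j - 1];          // right
      }
      cur[j] = cost + best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// [[Rcpp::export(name = ".dtw_cost_cpp")]]
double dtw_cost_cpp(NumericVector x, NumericVector y, int window = -1) {
  return dtw_core(REAL(x), x.size(), REAL(y), y.size(), window);
}

// Full symmetric pairwise DTW matrix over a list of sequences.
// [[Rcpp::export(name = ".dtw_pairwise_cpp")]]
NumericMatrix dtw_pairwise_cpp(List xs, int window = -1) {
  const int n = xs.size();
  NumericMatrix D(n, n);
  std::vector<NumericVector> v;
  v.reserve(n);
  for (int i = 0; i < n; ++i) v.push_back(as<NumericVector>(xs[i]));
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double d = dtw_core(REAL(v[i]), v[i].size(),
                                REAL(v[j]), v[j].size(), window);
      D(i, j) = d;
      D(j, i) = d;
    }
    Rcpp::checkUserInterrupt();
  }
  return D;
}

// DTW of every sequence in a list to one reference waveform.
// [[Rcpp::export(name = ".dtw_to_ref_cpp")]]
NumericVector dtw_to_ref_cpp(List xs, NumericVector ref, int window = -1) {
  const int n = xs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    NumericVector xi = as<NumericVector>(xs[i]);
    out[i] = dtw_core(REAL(xi), xi.size(), REAL(ref), ref.size(), window);
  }
  return out;
}
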