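#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Core pairwise computations for the Gehan rank objective/score.
// Residuals e_i = tau_i - X_i beta; delta_i = 1 iff uncensored.
// All loops are O(N^2) dense, which is acceptable at the sample sizes
// these models are used at (N up to a few thousand).

// Gehan objective G(beta) = sum_{i: delta_i = 1} sum_{i'} max(0, e_{i'} - e_i).
// Convex and piecewise linear in beta; ties contribute zero.
// [[Rcpp::export]]
double caft_objective_cpp(NumericVector e, IntegerVector delta) {
  int n = e.size();
  double g = 0.0;
  for (int i = 0; i < n; ++i) {
    if (delta[i] == 0) continue;
    double ei = e[i];
    for (int k = 0; k < n; ++k) {
      double d = e[k] - ei;
      if (d > 0) g += d;
    }
  }
  return g;
}

// a_i = R_{i+} - R_{+i} for R_{ii'} = delta_i * [ 1(e_i < e_i') + 0.5 * 1(e_i == e_i') ]
// (diagonal delta_i/2 cancels in the difference). The Gehan score is
// S(beta) = sum_i a_i X_i and the rank variance uses sigma2 = mean(a_i^2).
// [[Rcpp::export]]
NumericVector caft_rowcol_diff_cpp(NumericVector e, IntegerVector delta) {
  int n = e.size();
  NumericVector a(n);
  for (int i = 0; i < n; ++i) {
    double ai = 0.0;
    for (int k = 0; k < n; ++k) {
      if (k == i) continue;
      if (delta[i]) {
        if (e[i] < e[k]) ai += 1.0;
        else if (e[i] == e[k]) ai += 0.5;
      }
      if (delta[k]) {
        if (e[k] < e[i]) ai -= 1.0;
        else if (e[k] == e[i]) ai -= 0.5;
      }
    }
    a[i] = ai;
  }
  return a;
}

// Exact minimizer of the 1-D restriction g(t) = G(beta + t v):
//   g(t) = sum_{i: delta_i=1} sum_k max(0, (e_k - e_i) - t (w_k - w_i))
// with w = X v. g is convex piecewise linear; its derivative is a step
// function jumping by |c_p| at each kink t_p = d_p / c_p. The minimizer is
// located by a weighted-median style scan over sorted kinks; a flat optimal
// interval between two kinks is resolved to its midpoint (documented
// tie-break, downstream medians depend on it).
// Returns list(t, status): status 0 = unique-ish kink, 1 = flat interval
// (midpoint returned), 2 = objective flat/unbounded along v (t = 0).
// [[Rcpp::export]]
List caft_line_min_cpp(NumericVector e, NumericVector w, IntegerVector delta) {
  int n = e.size();
  std::vector<double> d, c;
  d.reserve(256); c.reserve(256);
  for (int i = 0; i < n; ++i) {
    if (delta[i] == 0) continue;
    for (int k = 0; k < n; ++k) {
      if (k == i) continue;
      double ck = w[k] - w[i];
      if (ck != 0.0) {
        d.push_back(e[k] - e[i]);
        c.push_back(ck);
      }
      // c == 0 terms are constant in t and ignored
    }
  }
  size_t P = d.size();
  if (P == 0) return List::create(_["t"] = 0.0, _["status"] = 2);

  // slope(t) = slope_at_minus_inf + sum_{p: t_p <= t} |c_p|
  double slope0 = 0.0, wtot = 0.0;
  std::vector<size_t> idx(P);
  std::vector<double> tk(P);
  for (size_t p = 0; p < P; ++p) {
    if (c[p] > 0) slope0 -= c[p];
    wtot += std::fabs(c[p]);
    tk[p] = d[p] / c[p];
    idx[p] = p;
  }
  std::sort(idx.begin(), idx.end(),
            [&](size_t a, size_t b) { return tk[a] < tk[b]; });

  double eps = 1e-12 * (wtot > 0 ? wtot : 1.0);
  double slope = slope0;
  for (size_t r = 0; r < P; ++r) {
    slope += std::fabs(c[idx[r]]);
    if (slope > eps) {
      return List::create(_["t"] = tk[idx[r]], _["status"] = 0);
    }
    if (slope >= -eps) {
      // derivative is (numerically) zero past this kink: flat stretch
      if (r + 1 < P) {
        double mid = 0.5 * (tk[idx[r]] + tk[idx[r + 1]]);
        return List::create(_["t"] = mid, _["status"] = 1);
      }
      // flat all the way to +inf: minimum attained from last kink on
      return List::create(_["t"] = tk[idx[r]], _["status"] = 2);
    }
  }
  // slope never reached zero (cannot happen: final slope >= 0 by construction)
  return List::create(_["t"] = tk[idx[P - 1]], _["status"] = 2);
}
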