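#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Hartigan's dip statistic: the minimum over unimodal CDFs G of
// sup_t |F_n(t) - G(t)|.
//
// Computed by bisection on the radius d. A unimodal G within d of the ECDF
// exists iff there are values g_j at the distinct sample points z_j with
//   g_j in [L_j, U_j],  L_j = max(0, C_j/n - d),  U_j = min(1, C_{j-1}/n + d)
// (two-sided limits of the ECDF jump at z_j), such that g is nondecreasing,
// convex up to some index k and concave from k on (the mode lies at z_k or in
// an adjacent gap; a kink at the mode is allowed, so no slope matching is
// required at k). Because both band edges are nondecreasing in j, the binding
// constraints reduce to forward extrapolations of the steepest (U_i -> L_j)
// line pairs, giving, for the convex side, a minimal achievable value
//   loL_k = max(L_k, max_{j<k} [L_j + s_j (z_k - z_j)]),
//   s_j = max(0, max_{i<j} (L_j - U_i)/(z_j - z_i)),
// achieved by the greatest convex minorant of U; the concave side is the
// mirror image (maximal achievable hiR_k). Feasibility holds iff some k has
// a feasible convex prefix, a feasible concave suffix, and loL_k <= hiR_k.

static const double TOL = 1e-12;

static bool dip_feasible(const std::vector<double>& z,
                         const std::vector<double>& cum,
                         double n, double d,
                         std::vector<double>& loL,
                         std::vector<double>& hiR) {
  const int m = (int)z.size();
  std::vector<double> L(m), U(m);
  for (int j = 0; j < m; ++j) {
    double lo = cum[j + 1] / n - d;
    double hi = cum[j] / n + d;
    L[j] = lo > 0.0 ? lo : 0.0;
    U[j] = hi < 1.0 ? hi : 1.0;
    if (L[j] > U[j] + TOL) return false;
  }
  // convex (left) side: minimal achievable value at each point
  std::vector<double> s(m, 0.0);
  for (int j = 1; j < m; ++j) {
    double best = 0.0;
    for (int i = 0; i < j; ++i) {
      double sl = (L[j] - U[i]) / (z[j] - z[i]);
      if (sl > best) best = sl;
    }
    s[j] = best;
  }
  std::vector<char> leftOK(m, 0);
  bool ok = true;
  for (int k = 0; k < m; ++k) {
    double v = L[k];
    for (int j = 0; j < k; ++j) {
      double cand = L[j] + s[j] * (z[k] - z[j]);
      if (cand > v) v = cand;
    }
    loL[k] = v;
    if (v > U[k] + TOL) ok = false;
    leftOK[k] = ok ? 1 : 0;
  }
  // concave (right) side, mirrored
  std::vector<double> t(m, 0.0);
  for (int j = m - 2; j >= 0; --j) {
    double best = 0.0;
    for (int l = j + 1; l < m; ++l) {
      double sl = (L[l] - U[j]) / (z[l] - z[j]);
      if (sl > best) best = sl;
    }
    t[j] = best;
  }
  std::vector<char> rightOK(m, 0);
  ok = true;
  for (int k = m - 1; k >= 0; --k) {
    double v = U[k];
    for (int j = k + 1; j < m; ++j) {
      double cand = U[j] - t[j] * (z[j] - z[k]);
      if (cand < v) v = cand;
    }
    hiR[k] = v;
    if (v < L[k] - TOL) ok = false;
    rightOK[k] = ok ? 1 : 0;
  }
  for (int k = 0; k < m; ++k)
    if (leftOK[k] && rightOK[k] && loL[k] <= hiR[k] + TOL) return true;
  return false;
}

// [[Rcpp::export]]
double dip_stat_cpp(NumericVector x) {
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end());
  const double n = (double)xs.size();
  std::vector<double> z;
  std::vector<double> cum;  // cum[j] = count of samples < z_j; cum[m] = n
  cum.push_back(0.0);
  size_t i = 0;
  while (i < xs.size()) {
    size_t j = i;
    while (j < xs.size() && xs[j] == xs[i]) ++j;
    z.push_back(xs[i]);
    cum.push_back((double)j);
    i = j;
  }
  const int m = (int)z.size();
  if (m < 2) stop("all values identical");
  std::vector<double> loL(m), hiR(m);
  // smallest d for which every band is nonempty (max half-jump)
  double lo = 0.0;
  for (int j = 0; j < m; ++j) {
    double half = (cum[j + 1] - cum[j]) / (2.0 * n);
    if (half > lo) lo = half;
  }
  if (dip_feasible(z, cum, n, lo, loL, hiR)) return lo;
  double hi = 0.5;
  for (int it = 0; it < 70 && hi - lo > 1e-12; ++it) {
    double mid = 0.5 * (lo + hi);
    if (dip_feasible(z, cum, n, mid, loL, hiR)) hi = mid;
    else lo = mid;
  }
  return hi;
}

// [[Rcpp::export]]
NumericVector dip_null_cpp(int n, int nboot) {
  NumericVector out(nboot);
  for (int b = 0; b < nboot; ++b) {
    NumericVector u = runif(n);
    out[b] = dip_stat_cpp(u);
  }
  return out;
}
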