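#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Gaussian KDE on an equally spaced grid by linear binning + truncated
// kernel convolution (kernel cut at 6 bandwidths; relative error < 1e-8).
// Output is renormalized to sum 1, so multiplicative constants are dropped.
static void kde_binned(const std::vector<double>& v, double lo, double dx,
                       int n, double bw, std::vector<double>& out) {
  std::vector<double> w(n, 0.0);
  for (size_t m = 0; m < v.size(); ++m) {
    double pos = (v[m] - lo) / dx;
    int i0 = (int)std::floor(pos);
    if (i0 < 0) i0 = 0;
    if (i0 > n - 2) i0 = n - 2;
    double f = pos - i0;
    w[i0] += 1.0 - f;
    w[i0 + 1] += f;
  }
  int L = (int)std::ceil(6.0 * bw / dx);
  if (L > n - 1) L = n - 1;
  std::vector<double> k(L + 1);
  for (int d = 0; d <= L; ++d) {
    double z = d * dx / bw;
    k[d] = std::exp(-0.5 * z * z);
  }
  // symmetric kernel: sweep offsets, sequential inner loops vectorize
  for (int g = 0; g < n; ++g) out[g] = w[g] * k[0];
  for (int d = 1; d <= L; ++d) {
    double kd = k[d];
    const double* wp = w.data();
    for (int g = d; g < n; ++g) out[g] += wp[g - d] * kd;
    for (int g = 0; g < n - d; ++g) out[g] += wp[g + d] * kd;
  }
  double total = 0.0;
  for (int g = 0; g < n; ++g) total += out[g];
  for (int g = 0; g < n; ++g) out[g] /= total;
}

// Jensen-Shannon divergence (base-2 logs) of two discrete distributions
static double jsd_discrete(const std::vector<double>& p,
                           const std::vector<double>& q) {
  const double ln2 = std::log(2.0);
  double acc = 0.0;
  for (size_t i = 0; i < p.size(); ++i) {
    double m = 0.5 * (p[i] + q[i]);
    if (p[i] > 0.0) acc += 0.5 * p[i] * std::log(p[i] / m) / ln2;
    if (q[i] > 0.0) acc += 0.5 * q[i] * std::log(q[i] / m) / ln2;
  }
  if (acc < 0.0) acc = 0.0;
  if (acc > 1.0) acc = 1.0;
  return acc;
}

// Similarity matrix 1 - sqrt(JSD) over all region pairs. For each pair the
// two samples are compared on a shared grid spanning the pooled range
// padded by 10% on each side. Bandwidths are supplied per region
// (Silverman's rule, computed in R).
// [[Rcpp::export(name = ".pairwise_similarity_cpp")]]
NumericMatrix pairwise_similarity_cpp(List values, NumericVector bws,
                                      int n_points) {
  int R = values.size();
  std::vector<std::vector<double>> vals(R);
  std::vector<double> vmin(R), vmax(R);
  for (int i = 0; i < R; ++i) {
    vals[i] = as<std::vector<double>>(values[i]);
    double lo = vals[i][0], hi = vals[i][0];
    for (size_t m = 1; m < vals[i].size(); ++m) {
      if (vals[i][m] < lo) lo = vals[i][m];
      if (vals[i][m] > hi) hi = vals[i][m];
    }
    vmin[i] = lo;
    vmax[i] = hi;
  }
  NumericMatrix W(R, R);
  for (int i = 0; i < R; ++i) W(i, i) = 1.0;
  std::vector<double> p(n_points), q(n_points);
  for (int i = 0; i < R - 1; ++i) {
    for (int j = i + 1; j < R; ++j) {
      double lo = std::min(vmin[i], vmin[j]);
      double hi = std::max(vmax[i], vmax[j]);
      double pad = 0.1 * (hi - lo);
      lo -= pad;
      hi += pad;
      double dx = (hi - lo) / (n_points - 1);
      kde_binned(vals[i], lo, dx, n_points, bws[i], p);
      kde_binned(vals[j], lo, dx, n_points, bws[j], q);
      double s = 1.0 - std::sqrt(jsd_discrete(p, q));
      W(i, j) = s;
      W(j, i) = s;
    }
  }
  return W;
}
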