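#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Natural cubic spline through (xs, ys), evaluated at integer abscissae
// 0..n_out-1. Knots must be strictly increasing. Thomas algorithm for the
// tridiagonal system of second derivatives; O(k + n_out) evaluation by a
// forward merge (both knot and evaluation grids are ascending).
static std::vector<double> natural_spline_eval(const std::vector<double>& xs,
                                               const std::vector<double>& ys,
                                               int n_out) {
  const int k = (int)xs.size();
  std::vector<double> out(n_out);
  if (k == 1) {
    std::fill(out.begin(), out.end(), ys[0]);
    return out;
  }
  if (k == 2) {
    double slope = (ys[1] - ys[0]) / (xs[1] - xs[0]);
    for (int i = 0; i < n_out; ++i) out[i] = ys[0] + slope * (i - xs[0]);
    return out;
  }
  // second derivatives M[0..k-1], natural BC: M[0] = M[k-1] = 0
  std::vector<double> h(k - 1), alpha(k), l(k), mu(k), z(k), M(k);
  for (int i = 0; i < k - 1; ++i) h[i] = xs[i + 1] - xs[i];
  alpha[0] = 0.0;
  // 6x the divided-difference jump: the system solves for M = s''
  for (int i = 1; i < k - 1; ++i)
    alpha[i] = 6.0 * ((ys[i + 1] - ys[i]) / h[i] - (ys[i] - ys[i - 1]) / h[i - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < k - 1; ++i) {
    l[i] = 2.0 * (xs[i + 1] - xs[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  M[k - 1] = 0.0;
  for (int i = k - 2; i >= 0; --i) M[i] = z[i] - mu[i] * M[i + 1];

  int seg = 0;
  for (int i = 0; i < n_out; ++i) {
    double x = (double)i;
    while (seg < k - 2 && x > xs[seg + 1]) ++seg;
    double hseg = h[seg];
    double A = (xs[seg + 1] - x) / hseg;
    double B = (x - xs[seg]) / hseg;
    out[i] = A * ys[seg] + B * ys[seg + 1] +
      ((A * A * A - A) * M[seg] + (B * B * B - B) * M[seg + 1]) *
      (hseg * hseg) / 6.0;
  }
  return out;
}

// Local extrema with plateau-middle policy: runs of equal consecutive values
// collapse to one candidate at the run's middle index. Only interior runs
// (not touching either end) qualify. 0-based indices.
static void find_extrema_core(const double* x, int n,
                              std::vector<int>& maxima,
                              std::vector<int>& minima) {
  maxima.clear(); minima.clear();
  if (n < 3) return;
  int i = 0;
  double prev_val = 0.0; bool have_prev = false;
  while (i < n) {            // iterate over runs of equal values
    int j = i;
    while (j + 1 < n && x[j + 1] == x[i]) ++j;   // run i..j
    if (i > 0 && j < n - 1 && have_prev) {
      double next_val = x[j + 1];
      double v = x[i];
      if (v > prev_val && v > next_val)
        maxima.push_back((i + j) / 2);
      else if (v < prev_val && v < next_val)
        minima.push_back((i + j) / 2);
    }
    prev_val = x[i]; have_prev = true;
    i = j + 1;
  }
}

// [[Rcpp::export(name = ".find_extrema_cpp")]]
List find_extrema_cpp(NumericVector x) {
  std::vector<int> mx, mn;
  find_extrema_core(REAL(x), x.size(), mx, mn);
  IntegerVector mxr(mx.size()), mnr(mn.size());
  for (size_t i = 0; i < mx.size(); ++i) mxr[i] = mx[i] + 1;  // 1-based for R
  for (size_t i = 0; i < mn.size(); ++i) mnr[i] = mn[i] + 1;
  return List::create(_["maxima"] = mxr, _["minima"] = mnr);
}

// Mirror the two extrema nearest each end across the boundary sample
// (index 0 on the left, n-1 on the right) to anchor the spline ends.
static void mirror_extend(const std::vector<int>& idx, const double* x, int n,
                          std::vector<double>& xs, std::vector<double>& ys) {
  xs.clear(); ys.clear();
  const int k = (int)idx.size();
  // left extension: reflect nearest (up to two) extrema about 0
  int nl = std::min(2, k);
  for (int i = nl - 1; i >= 0; --i) {
    if (idx[i] > 0) { xs.push_back(-(double)idx[i]); ys.push_back(x[idx[i]]); }
  }
  for (int i = 0; i < k; ++i) { xs.push_back((double)idx[i]); ys.push_back(x[idx[i]]); }
  int nr = std::min(2, k);
  for (int i = 0; i < nr; ++i) {
    int j = k - 1 - i;
    if (idx[j] < n - 1) {
      xs.push_back(2.0 * (n - 1) - idx[j]); ys.push_back(x[idx[j]]);
    }
  }
  // xs built left block in reverse then ascending core then right: fix order
  // (left block was pushed most-negative last; rebuild properly)
  std::vector<std::pair<double,double>> pts(xs.size());
  for (size_t i = 0; i < xs.size(); ++i) pts[i] = std::make_pair(xs[i], ys[i]);
  std::sort(pts.begin(), pts.end());
  xs.clear(); ys.clear();
  double last = -1e300;
  for (size_t i = 0; i < pts.size(); ++i) {
    if (pts[i].first > last) {               // drop duplicate abscissae
      xs.push_back(pts[i].first); ys.push_back(pts[i].second);
      last = pts[i].first;
    }
  }
}

// upper/lower cubic-spline envelopes and their mean; returns false when the
// signal is a monotone residue (fewer than 2 maxima or 2 minima).
static bool envelope_core(const double* x, int n,
                          std::vector<double>& upper,
                          std::vector<double>& lower,
                          std::vector<double>& mean) {
  std::vector<int> mx, mn;
  find_extrema_core(x, n, mx, mn);
  if ((int)mx.size() < 2 || (int)mn.size() < 2) return false;
  std::vector<double> xs, ys;
  mirror_extend(mx, x, n, xs, ys);
  upper = natural_spline_eval(xs, ys, n);
  mirror_extend(mn, x, n, xs, ys);
  lower = natural_spline_eval(xs, ys, n);
  mean.resize(n);
  for (int i = 0; i < n; ++i) mean[i] = 0.5 * (upper[i] + lower[i]);
  return true;
}

// [[Rcpp::export(name = ".envelope_cpp")]]
List envelope_cpp(NumericVector x) {
  std::vector<double> up, lo, me;
  bool ok = envelope_core(REAL(x), x.size(), up, lo, me);
  if (!ok) return List::create(_["ok"] = false);
  return List::create(_["ok"] = true,
                      _["upper"] = NumericVector(up.begin(), up.end()),
                      _["lower"] = NumericVector(lo.begin(), lo.end()),
                      _["mean"]  = NumericVector(me.begin(), me.end()));
}

// One sifted IMF candidate via the Cauchy criterion
// SD = sum((h_prev - h)^2) / sum(h_prev^2) < sd_tol, capped at max_sift.
// Returns false if the input is already a monotone residue.
static bool sift_one(std::vector<double>& h, double sd_tol, int max_sift) {
  const int n = (int)h.size();
  std::vector<double> up, lo, me;
  for (int it = 0; it < max_sift; ++it) {
    if (!envelope_core(h.data(), n, up, lo, me)) return it > 0;
    double num = 0.0, den = 0.0;
    for (int i = 0; i < n; ++i) {
      num += me[i] * me[i];
      den += h[i] * h[i];
      h[i] -= me[i];
    }
    if (den <= 0.0) return true;
    if (num / den < sd_tol) return true;
  }
  return true;
}

// EMD driver. force_count=true pads with zero IMFs once the residue turns
// monotone, so ensemble members stay index-aligned.
static void emd_core(const std::vector<double>& x, int max_imfs,
                     double sd_tol, int max_sift, bool force_count,
                     std::vector<std::vector<double>>& imfs,
                     std::vector<double>& residue) {
  const int n = (int)x.size();
  residue = x;
  imfs.clear();
  for (int m = 0; m < max_imfs; ++m) {
    std::vector<double> h = residue;
    std::vector<int> mx, mn;
    find_extrema_core(residue.data(), n, mx, mn);
    if ((int)mx.size() < 2 || (int)mn.size() < 2) break;  // monotone residue
    if (!sift_one(h, sd_tol, max_sift)) break;
    imfs.push_back(h);
    for (int i = 0; i < n; ++i) residue[i] -= h[i];
  }
  if (force_count) {
    while ((int)imfs.size() < max_imfs)
      imfs.push_back(std::vector<double>(n, 0.0));
  }
}

// [[Rcpp::export(name = ".emd_cpp")]]
List emd_cpp(NumericVector x, int max_imfs, double sd_tol, int max_sift,
             bool force_count) {
  std::vector<double> xv(x.begin(), x.end());
  std::vector<std::vector<double>> imfs;
  std::vector<double> residue;
  emd_core(xv, max_imfs, sd_tol, max_sift, force_count, imfs, residue);
  const int n = (int)xv.size(), m = (int)imfs.size();
  NumericMatrix im(n, m);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) im(i, j) = imfs[j][i];
  return List::create(_["imfs"] = im,
                      _["residue"] = NumericVector(residue.begin(), residue.end()));
}

// Ensemble EMD: column j of `noise` is the pre-scaled white-noise series for
// ensemble member j. Every member is forced to max_imfs IMFs; the returned
// IMFs and residue are ensemble means, so their sum reconstructs the
// ensemble-mean input x + rowMeans(noise).
// [[Rcpp::export(name = ".eemd_cpp")]]
List eemd_cpp(NumericVector x, NumericMatrix noise, int max_imfs,
              double sd_tol, int max_sift) {
  const int n = x.size(), N = noise.ncol();
  NumericMatrix acc(n, max_imfs);
  NumericVector res_acc(n);
  std::vector<double> xv(n);
  std::vector<std::vector<double>> imfs;
  std::vector<double> residue;
  for (int j = 0; j < N; ++j) {
    for (int i = 0; i < n; ++i) xv[i] = x[i] + noise(i, j);
    emd_core(xv, max_imfs, sd_tol, max_sift, true, imfs, residue);
    for (int m = 0; m < max_imfs; ++m)
      for (int i = 0; i < n; ++i) acc(i, m) += imfs[m][i];
    for (int i = 0; i < n; ++i) res_acc[i] += residue[i];
    if (j % 16 == 0) Rcpp::checkUserInterrupt();
  }
  for (int m = 0; m < max_imfs; ++m)
    for (int i = 0; i < n; ++i) acc(i, m) /= N;
  for (int i = 0; i < n; ++i) res_acc[i] /= N;
  return List::create(_["imfs"] = acc, _["residue"] = res_acc);
}
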