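#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Locate local maxima and minima via sign changes of the first difference.
// Zero differences (plateaus) inherit the preceding non-zero sign, so a
// rising-plateau-falling shape yields one maximum at the plateau end.
static void find_extrema(const std::vector<double>& x,
                         std::vector<int>& maxi, std::vector<int>& mini) {
  const int n = (int)x.size();
  maxi.clear(); mini.clear();
  if (n < 3) return;
  std::vector<int> s(n - 1, 0);
  int prev = 0;
  for (int i = 0; i < n - 1; ++i) {
    double d = x[i + 1] - x[i];
    int sg = (d > 0) - (d < 0);
    if (sg == 0) sg = prev;
    s[i] = sg;
    prev = sg;
  }
  for (int i = 0; i < n - 2; ++i) {
    if (s[i] > 0 && s[i + 1] < 0) maxi.push_back(i + 1);
    else if (s[i] < 0 && s[i + 1] > 0) mini.push_back(i + 1);
  }
}

// Natural cubic spline through (t, y), evaluated at 0..n-1.
// Knots must be strictly increasing; linear extrapolation outside the range
// (unreachable once mirror extension supplies knots beyond both ends).
static void spline_eval(const std::vector<double>& t, const std::vector<double>& y,
                        int n, std::vector<double>& out) {
  const int k = (int)t.size();
  out.assign(n, 0.0);
  if (k == 1) { std::fill(out.begin(), out.end(), y[0]); return; }
  if (k == 2) {
    double slope = (y[1] - y[0]) / (t[1] - t[0]);
    for (int i = 0; i < n; ++i) out[i] = y[0] + slope * (i - t[0]);
    return;
  }
  // second derivatives M, natural BC: M[0] = M[k-1] = 0
  std::vector<double> h(k - 1), alpha(k, 0.0), l(k), mu(k), z(k), M(k);
  for (int i = 0; i < k - 1; ++i) h[i] = t[i + 1] - t[i];
  for (int i = 1; i < k - 1; ++i)
    alpha[i] = 3.0 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < k - 1; ++i) {
    l[i] = 2.0 * (t[i + 1] - t[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  M[k - 1] = 0.0;
  for (int i = k - 2; i >= 0; --i) M[i] = z[i] - mu[i] * M[i + 1];

  int seg = 0;
  for (int i = 0; i < n; ++i) {
    double xv = (double)i;
    if (xv <= t[0]) {
      double slope = (y[1] - y[0]) / h[0] - h[0] * (2.0 * M[0] + M[1]) / 6.0;
      out[i] = y[0] + slope * (xv - t[0]);
      continue;
    }
    if (xv >= t[k - 1]) {
      double hl = h[k - 2];
      double slope = (y[k - 1] - y[k - 2]) / hl + hl * (M[k - 2] + 2.0 * M[k - 1]) / 6.0;
      out[i] = y[k - 1] + slope * (xv - t[k - 1]);
      continue;
    }
    while (seg < k - 2 && t[seg + 1] < xv) ++seg;
    double a = t[seg], b = t[seg + 1], hh = b - a;
    double A = (b - xv) / hh, B = (xv - a) / hh;
    out[i] = A * y[seg] + B * y[seg + 1] +
      ((A * A * A - A) * M[seg] + (B * B * B - B) * M[seg + 1]) * hh * hh / 6.0;
  }
}

// Mirror-extend `next` extrema of each edge about the end samples before
// spline fitting, suppressing boundary swings.
static void build_knots(const std::vector<int>& idx, const std::vector<double>& x,
                        int n, int next,
                        std::vector<double>& t, std::vector<double>& y) {
  const int k = (int)idx.size();
  t.clear(); y.clear();
  // left mirror about sample 0
  for (int j = std::min(next, k) - 1; j >= 0; --j) {
    if (idx[j] > 0) { t.push_back(-(double)idx[j]); y.push_back(x[idx[j]]); }
  }
  for (int j = 0; j < k; ++j) { t.push_back((double)idx[j]); y.push_back(x[idx[j]]); }
  // right mirror about sample n-1
  for (int j = k - 1; j >= std::max(0, k - next); --j) {
    if (idx[j] < n - 1) {
      t.push_back(2.0 * (n - 1) - (double)idx[j]); y.push_back(x[idx[j]]);
    }
  }
  // enforce strictly increasing (mirrors of coincident edge extrema)
  std::vector<double> tt, yy;
  for (size_t j = 0; j < t.size(); ++j) {
    if (tt.empty() || t[j] > tt.back() + 1e-9) { tt.push_back(t[j]); yy.push_back(y[j]); }
  }
  t.swap(tt); y.swap(yy);
}

// One sifting pass: returns false when envelopes cannot be built.
static bool envelope_mean(const std::vector<double>& h, std::vector<double>& m) {
  const int n = (int)h.size();
  std::vector<int> maxi, mini;
  find_extrema(h, maxi, mini);
  if ((int)maxi.size() < 2 || (int)mini.size() < 2) return false;
  std::vector<double> t, y, eu, el;
  build_knots(maxi, h, n, 2, t, y);
  spline_eval(t, y, n, eu);
  build_knots(mini, h, n, 2, t, y);
  spline_eval(t, y, n, el);
  m.resize(n);
  for (int i = 0; i < n; ++i) m[i] = 0.5 * (eu[i] + el[i]);
  return true;
}

//' @noRd
// [[Rcpp::export(name = ".emd_cpp")]]
List emd_cpp(NumericVector x, double sd_thresh = 0.2,
             int max_sift = 100, int max_imf = 12) {
  const int n = x.size();
  std::vector<double> r(x.begin(), x.end());
  std::vector<std::vector<double> > imfs;

  while ((int)imfs.size() < max_imf) {
    std::vector<int> maxi, mini;
    find_extrema(r, maxi, mini);
    if ((int)maxi.size() < 2 || (int)mini.size() < 2) break;

    std::vector<double> h(r), m, hnew(n);
    bool extracted = false;
    for (int it = 0; it < max_sift; ++it) {
      if (!envelope_mean(h, m)) break;
      double num = 0.0, den = 0.0;
      for (int i = 0; i < n; ++i) {
        hnew[i] = h[i] - m[i];
        num += m[i] * m[i];        // (h - hnew)^2 = m^2
        den += h[i] * h[i];
      }
      h.swap(hnew);
      extracted = true;
      if (num / (den + 1e-300) < sd_thresh) break;
    }
    if (!extracted) break;
    imfs.push_back(h);
    for (int i = 0; i < n; ++i) r[i] -= h[i];
  }

  const int k = (int)imfs.size();
  NumericMatrix out(k, n);
  for (int j = 0; j < k; ++j)
    for (int i = 0; i < n; ++i) out(j, i) = imfs[j][i];
  return List::create(_["imfs"] = out,
                      _["residual"] = NumericVector(r.begin(), r.end()));
}
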