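#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sample entropy with absolute tolerance r. Templates of length m and m+1
// both range over i = 0..N-m-1 so the conditional probability is well
// defined; self-matches excluded; Chebyshev distance.
// Returns +Inf when no (m+1)-matches exist (flagged upstream).
//' @noRd
// [[Rcpp::export(name = ".sampen_cpp")]]
double sampen_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // number of usable templates
  if (nt < 2) return NA_REAL;
  long long A = 0, B = 0;
  const double* u = x.begin();
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(u[i + k] - u[j + k]);
        if (a > d) d = a;
      }
      if (d <= r) {
        ++B;
        double a = std::fabs(u[i + m] - u[j + m]);
        if (a <= d || a <= r) {
          if (std::max(d, a) <= r) ++A;
        }
      }
    }
  }
  if (B == 0 || A == 0) return R_PosInf;
  return -std::log((double)A / (double)B);
}

// Fuzzy entropy: mean-subtracted embeddings, Chebyshev distances, similarity
// exp(-d^nexp / r), phi as the double average over ordered pairs (i != j).
// Both phi^m and phi^{m+1} use i = 0..N-m-1 so the two averages are over the
// same template set.
//' @noRd
// [[Rcpp::export(name = ".fuzzyen_cpp")]]
double fuzzyen_cpp(NumericVector x, int m, double nexp, double r) {
  const int n = x.size();
  const int nt = n - m;  // vectors of length m and of length m+1
  if (nt < 2) return NA_REAL;
  const double* u = x.begin();

  // prefix sums for window means
  std::vector<double> cs(n + 1, 0.0);
  for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + u[i];
  std::vector<double> mu_m(nt), mu_m1(nt);
  for (int i = 0; i < nt; ++i) {
    mu_m[i] = (cs[i + m] - cs[i]) / m;
    mu_m1[i] = (cs[i + m + 1] - cs[i]) / (m + 1);
  }

  double phi_m = 0.0, phi_m1 = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double dm = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs((u[i + k] - mu_m[i]) - (u[j + k] - mu_m[j]));
        if (a > dm) dm = a;
      }
      double dm1 = 0.0;
      for (int k = 0; k <= m; ++k) {
        double a = std::fabs((u[i + k] - mu_m1[i]) - (u[j + k] - mu_m1[j]));
        if (a > dm1) dm1 = a;
      }
      // nexp == 2 is the default and sits in a hot O(N^2) loop
      double pm  = (nexp == 2.0) ? dm * dm :
                   (nexp == 1.0) ? dm : std::pow(dm, nexp);
      double pm1 = (nexp == 2.0) ? dm1 * dm1 :
                   (nexp == 1.0) ? dm1 : std::pow(dm1, nexp);
      phi_m  += std::exp(-pm / r);
      phi_m1 += std::exp(-pm1 / r);
    }
  }
  const double npairs = 0.5 * (double)nt * (double)(nt - 1);
  phi_m /= npairs;
  phi_m1 /= npairs;
  if (phi_m <= 0.0 || phi_m1 <= 0.0) return R_PosInf;
  return std::log(phi_m) - std::log(phi_m1);
}
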