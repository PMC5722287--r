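#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Chebyshev distance between templates starting at i and j, length m.
static inline double cheb_dist(const double* x, int i, int j, int m) {
  double d = 0.0;
  for (int k = 0; k < m; ++k) {
    double a = std::fabs(x[i + k] - x[j + k]);
    if (a > d) d = a;
  }
  return d;
}

// Approximate entropy (Pincus): AE = Phi^m(r) - Phi^{m+1}(r), where
// Phi^m = mean_i log(C_i^m) and C_i^m is the fraction of templates
// (self-match included) within Chebyshev distance r of template i.
// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  int N = x.size();
  if (N <= m + 1) stop("series too short for embedding dimension m");
  if (r <= 0.0) return 0.0;
  const double* px = x.begin();
  double phi[2];
  for (int s = 0; s < 2; ++s) {
    int mm = m + s;
    int n_tpl = N - mm + 1;
    double acc = 0.0;
    for (int i = 0; i < n_tpl; ++i) {
      int cnt = 0;
      for (int j = 0; j < n_tpl; ++j) {
        double d = 0.0;
        bool within = true;
        for (int k = 0; k < mm; ++k) {
          d = std::fabs(px[i + k] - px[j + k]);
          if (d > r) { within = false; break; }
        }
        if (within) ++cnt;
      }
      acc += std::log((double)cnt / (double)n_tpl);
    }
    phi[s] = acc / (double)n_tpl;
  }
  return phi[0] - phi[1];
}

// Sample entropy (Richman & Moorman): B = matching template pairs at
// length m, A at length m+1, both over the N-m templates with indices
// 0..N-m-1, self-matches excluded; SE = -log(A/B).
// A == 0 gives the finite sentinel log(B) (i.e. -log(1/B)); B == 0 gives 0.
// [[Rcpp::export]]
double sampen_cpp(NumericVector x, int m, double r) {
  int N = x.size();
  if (N <= m + 1) stop("series too short for embedding dimension m");
  if (r <= 0.0) return 0.0;
  const double* px = x.begin();
  long long A = 0, B = 0;
  int n_tpl = N - m;
  for (int i = 0; i < n_tpl - 1; ++i) {
    for (int j = i + 1; j < n_tpl; ++j) {
      bool within = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(px[i + k] - px[j + k]) > r) { within = false; break; }
      }
      if (within) {
        ++B;
        if (std::fabs(px[i + m] - px[j + m]) <= r) ++A;
      }
    }
  }
  if (B == 0) return 0.0;
  if (A == 0) return std::log((double)B);
  return -std::log((double)A / (double)B);
}

// Fuzzy entropy (Chen): templates are mean-centred, hard threshold replaced
// by the graded membership exp(-(d/r)^n) with Chebyshev d; both template
// lengths use the N-m templates with indices 0..N-m-1.
// FE = log(phi^m) - log(phi^{m+1}).
// [[Rcpp::export]]
double fuzzyen_cpp(NumericVector x, int m, double r, double n_grad) {
  int N = x.size();
  if (N <= m + 1) stop("series too short for embedding dimension m");
  if (r <= 0.0) return 0.0;
  int n_tpl = N - m;
  double phi[2];
  for (int s = 0; s < 2; ++s) {
    int mm = m + s;
    // mean-centred templates, contiguous storage
    std::vector<double> u((size_t)n_tpl * mm);
    for (int i = 0; i < n_tpl; ++i) {
      double mu = 0.0;
      for (int k = 0; k < mm; ++k) mu += x[i + k];
      mu /= mm;
      for (int k = 0; k < mm; ++k) u[(size_t)i * mm + k] = x[i + k] - mu;
    }
    double acc = 0.0;
    for (int i = 0; i < n_tpl - 1; ++i) {
      for (int j = i + 1; j < n_tpl; ++j) {
        double d = cheb_dist(u.data(), i * mm, j * mm, mm);
        acc += std::exp(-std::pow(d / r, n_grad));
      }
    }
    phi[s] = 2.0 * acc / ((double)n_tpl * (n_tpl - 1));
  }
  if (phi[0] <= 0.0 || phi[1] <= 0.0) return 0.0;
  return std::log(phi[0]) - std::log(phi[1]);
}
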