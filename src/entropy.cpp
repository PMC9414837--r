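#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template-match counts for sample entropy (Chebyshev distance, self-matches
// excluded). Returns B = #pairs matching at length m, A = #pairs matching at
// length m+1, counting unordered pairs i < j over the N - m templates so that
// both counts run over a common template set.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m;  // templates of length m+1 start at 0..nt-1
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double dm = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(x[i + k] - x[j + k]);
        if (d > dm) dm = d;
        if (dm >= r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      double d = std::fabs(x[i + m] - x[j + m]);
      if (d > dm) dm = d;
      if (dm < r) A += 1.0;
    }
  }
  return NumericVector::create(_["A"] = A, _["B"] = B);
}

// Mean fuzzy membership phi^m: templates of length m are de-meaned, pairwise
// Chebyshev distances d feed the membership exp(-(d/r)^nf), averaged over all
// unordered pairs (self-matches excluded).
// [[Rcpp::export]]
double fuzzy_phi(NumericVector x, int m, double nf, double r) {
  int n = x.size();
  int nt = n - m + 1;
  if (nt < 2) return NA_REAL;
  // de-meaned templates
  NumericMatrix tpl(nt, m);
  for (int i = 0; i < nt; ++i) {
    double mu = 0.0;
    for (int k = 0; k < m; ++k) mu += x[i + k];
    mu /= m;
    for (int k = 0; k < m; ++k) tpl(i, k) = x[i + k] - mu;
  }
  double acc = 0.0;
  long cnt = 0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double dm = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(tpl(i, k) - tpl(j, k));
        if (d > dm) dm = d;
      }
      acc += std::exp(-std::pow(dm / r, nf));
      ++cnt;
    }
  }
  return acc / (double)cnt;
}
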