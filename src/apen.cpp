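#include <Rcpp.h>
using namespace Rcpp;

// Template-match statistics for approximate entropy. Returns
// c(Phi^m(r), Phi^(m+1)(r)) with the standard N - m + 1 template count,
// self-matches included, natural logarithms. A pair matching at embedding
// dimension m + 1 necessarily matches at dimension m, so both counts are
// accumulated in one sweep over ordered pairs.
// [[Rcpp::export]]
NumericVector apen_phis_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nv = n - m + 1;   // templates at dimension m
  const int nv2 = n - m;      // templates at dimension m + 1
  if (nv2 < 1) stop("series too short for embedding dimension m + 1");
  std::vector<int> c1(nv, 1), c2(nv2, 1);  // self-matches
  for (int i = 0; i < nv; ++i) {
    for (int j = i + 1; j < nv; ++j) {
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { ok = false; break; }
      }
      if (!ok) continue;
      ++c1[i]; ++c1[j];
      if (j < nv2 && std::fabs(x[i + m] - x[j + m]) <= r) {
        ++c2[i]; ++c2[j];
      }
    }
  }
  double phi_m = 0.0, phi_m1 = 0.0;
  for (int i = 0; i < nv; ++i) phi_m += std::log((double)c1[i] / nv);
  phi_m /= nv;
  for (int i = 0; i < nv2; ++i) phi_m1 += std::log((double)c2[i] / nv2);
  phi_m1 /= nv2;
  return NumericVector::create(phi_m, phi_m1);
}
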