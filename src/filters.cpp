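// Direct-form II transposed IIR filtering with optional initial conditions,
// the workhorse behind single-pass and zero-phase filtering.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".iir_df2t_cpp")]]
NumericVector iir_df2t_cpp(NumericVector b, NumericVector a, NumericVector x,
                           NumericVector zi) {
  int n = x.size();
  int nf = std::max(b.size(), a.size());
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  std::vector<double> z(nf - 1, 0.0);
  for (int i = 0; i < zi.size() && i < nf - 1; ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + (nf > 1 ? z[0] : 0.0);
    for (int k = 0; k < nf - 2; ++k) {
      z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
    }
    if (nf > 1) z[nf - 2] = bb[nf - 1] * xi - aa[nf - 1] * yi;
    y[i] = yi;
  }
  return y;
}
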