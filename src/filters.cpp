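#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with initial state zi (length n-1,
// n = max(length(a), length(b))). Coefficients must be pre-normalised so
// a[0] == 1. Returns the filtered signal only; the final state is not needed
// by the zero-phase driver because each pass starts from a scaled steady state.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  int nb = b.size(), na = a.size();
  int n = std::max(nb, na);
  std::vector<double> bb(n, 0.0), aa(n, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  std::vector<double> z(n - 1, 0.0);
  for (int i = 0; i < (int)zi.size() && i < n - 1; ++i) z[i] = zi[i];

  int len = x.size();
  NumericVector y(len);
  for (int m = 0; m < len; ++m) {
    double xm = x[m];
    double ym = bb[0] * xm + z[0];
    for (int i = 0; i < n - 2; ++i)
      z[i] = bb[i + 1] * xm + z[i + 1] - aa[i + 1] * ym;
    z[n - 2] = bb[n - 1] * xm - aa[n - 1] * ym;
    y[m] = ym;
  }
  return y;
}
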