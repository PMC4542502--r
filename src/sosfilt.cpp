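#include <Rcpp.h>
using namespace Rcpp;

// Second-order section (direct form II transposed) with initial state,
// y[i] = b0 x[i] + z1;  z1 = b1 x[i] - a1 y[i] + z2;  z2 = b2 x[i] - a2 y[i].
// Initial conditions follow the steady-state construction used by filtfilt
// implementations (state scaled to the first input sample by the caller).

// [[Rcpp::export]]
NumericVector biquad_filter(NumericVector b, NumericVector a,
                            NumericVector x, NumericVector zi) {
  const int n = x.size();
  NumericVector y(n);
  double b0 = b[0], b1 = b[1], b2 = b[2];
  double a1 = a[1], a2 = a[2];
  double z1 = zi[0], z2 = zi[1];
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b0 * xi + z1;
    z1 = b1 * xi - a1 * yi + z2;
    z2 = b2 * xi - a2 * yi;
    y[i] = yi;
  }
  return y;
}
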