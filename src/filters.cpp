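#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter applied independently to each
// column of x. Zero initial conditions.
// [[Rcpp::export]]
NumericMatrix iir_filter_mat(NumericVector b, NumericVector a,
                             NumericMatrix x) {
  int n = x.nrow(), p = x.ncol();
  int nb = b.size(), na = a.size();
  int nz = std::max(nb, na) - 1;
  if (a[0] == 0.0) stop("a[0] must be non-zero");
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a[0];
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a[0];
  NumericMatrix y(n, p);
  for (int j = 0; j < p; ++j) {
    std::vector<double> z(nz, 0.0);
    for (int t = 0; t < n; ++t) {
      double xi = x(t, j);
      double yi = bb[0] * xi + z[0];
      for (int k = 0; k < nz - 1; ++k)
        z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
      z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
      y(t, j) = yi;
    }
  }
  return y;
}
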