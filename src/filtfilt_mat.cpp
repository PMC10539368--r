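#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Zero-phase IIR filtering of every column of a matrix, replicating
// signal::filtfilt()'s scheme exactly: pad with 2*max(length(a),
// length(b)) trailing zeros, forward filter (zero initial conditions,
// direct form II transposed), reverse, filter again, reverse, truncate.
// [[Rcpp::export]]
NumericMatrix filtfilt_mat(NumericVector b, NumericVector a,
                           NumericMatrix X) {
  const int n = X.nrow(), m = X.ncol();
  const int ord = std::max(a.size(), b.size());
  const int npad = 2 * ord;
  const int N = n + npad;
  std::vector<double> bb(ord, 0.0), aa(ord, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i] / a[0];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i] / a[0];
  const int M = ord - 1;
  std::vector<double> x(N), y(N), z(M);
  NumericMatrix Y(n, m);
  for (int c = 0; c < m; ++c) {
    for (int i = 0; i < n; ++i) x[i] = X(i, c);
    std::fill(x.begin() + n, x.end(), 0.0);
    for (int pass = 0; pass < 2; ++pass) {
      std::fill(z.begin(), z.end(), 0.0);
      for (int i = 0; i < N; ++i) {
        const double xi = x[i];
        const double yi = bb[0] * xi + (M > 0 ? z[0] : 0.0);
        for (int j = 0; j < M - 1; ++j) {
          z[j] = z[j + 1] + bb[j + 1] * xi - aa[j + 1] * yi;
        }
        if (M > 0) z[M - 1] = bb[M] * xi - aa[M] * yi;
        y[i] = yi;
      }
      std::reverse(y.begin(), y.end());
      x = y;
    }
    for (int i = 0; i < n; ++i) Y(i, c) = x[i];
  }
  return Y;
}
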