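// Row-wise Euclidean projection onto the probability simplex
// (sort-based exact algorithm), the inner step of the ancestry ALS.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".proj_simplex_rows_cpp")]]
NumericMatrix proj_simplex_rows_cpp(NumericMatrix X) {
  const int n = X.nrow(), K = X.ncol();
  NumericMatrix out(n, K);
  if (K == 1) {
    std::fill(out.begin(), out.end(), 1.0);
    return out;
  }
  std::vector<double> u(K);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < K; ++j) u[j] = X(i, j);
    std::sort(u.begin(), u.end(), std::greater<double>());
    double css = 0.0, theta = 0.0;
    int rho = 0;
    for (int j = 0; j < K; ++j) {
      css += u[j];
      if (u[j] - (css - 1.0) / (j + 1) > 0) {
        rho = j + 1;
        theta = (css - 1.0) / (j + 1);
      }
    }
    (void)rho;
    for (int j = 0; j < K; ++j) {
      out(i, j) = std::max(X(i, j) - theta, 0.0);
    }
  }
  return out;
}
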