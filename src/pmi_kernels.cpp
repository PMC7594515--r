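#include <Rcpp.h>
using namespace Rcpp;

// Unnormalized Gaussian kernel matrix K[l, m] = exp(-(x_l - x_m)^2 / (2 h^2)).
// Shared across every edge incident to a node, so it is computed once per
// node and reused. Written column-wise for cache-friendly streaming; the
// matrix is symmetric but recomputing the upper triangle is cheaper than
// strided mirror writes.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_kernel_matrix(NumericVector x, double h) {
  const int n = x.size();
  const double inv2h2 = 1.0 / (2.0 * h * h);
  NumericMatrix K(n, n);
  double *col = K.begin();
  for (int m = 0; m < n; ++m, col += n) {
    const double xm = x[m];
    for (int l = 0; l < n; ++l) {
      const double d = x[l] - xm;
      col[l] = std::exp(-d * d * inv2h2);
    }
  }
  return K;
}

// Exact univariate normal-kernel density at the sample's own points.
// [[Rcpp::export]]
NumericVector cpp_kde_self(NumericVector x, double h) {
  const int n = x.size();
  const double inv2h2 = 1.0 / (2.0 * h * h);
  const double norm = 1.0 / (n * h * std::sqrt(2.0 * M_PI));
  NumericVector out(n);
  for (int m = 0; m < n; ++m) {
    const double xm = x[m];
    double acc = 0.0;
    for (int l = 0; l < n; ++l) {
      const double d = x[l] - xm;
      acc += std::exp(-d * d * inv2h2);
    }
    out[m] = acc;
  }
  return norm * out;
}

// Joint density at the sample points for one edge from the two cached
// per-node kernel matrices: scale * rowMeans(Ki * Kj).
// [[Rcpp::export]]
NumericVector cpp_pair_density(NumericMatrix Ki, NumericMatrix Kj,
                               double scale) {
  const int n = Ki.nrow();
  NumericVector out(n);
  const double *pi = Ki.begin();
  const double *pj = Kj.begin();
  for (int m = 0; m < n; ++m, pi += n, pj += n) {
    for (int l = 0; l < n; ++l) out[l] += pi[l] * pj[l];
  }
  return scale / n * out;
}
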