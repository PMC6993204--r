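#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Dynamic time warping with squared-Euclidean local cost and the symmetric
// step pattern {(1,1),(1,0),(0,1)}. Returns the accumulated cost and the
// optimal warping path as 1-based index vectors into a and b.
// [[Rcpp::export]]
List dtw_core(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow(), d = a.ncol();
  if (b.ncol() != d) stop("profiles must have the same number of channels");
  if (n < 2 || m < 2) stop("profiles must have length >= 2");

  std::vector<double> D((size_t)n * m);
  auto cost = [&](int i, int j) {
    double s = 0.0;
    for (int k = 0; k < d; ++k) {
      double diff = a(i, k) - b(j, k);
      s += diff * diff;
    }
    return s;
  };

  D[0] = cost(0, 0);
  for (int j = 1; j < m; ++j) D[j] = D[j - 1] + cost(0, j);
  for (int i = 1; i < n; ++i) {
    D[(size_t)i * m] = D[(size_t)(i - 1) * m] + cost(i, 0);
    for (int j = 1; j < m; ++j) {
      double up   = D[(size_t)(i - 1) * m + j];
      double left = D[(size_t)i * m + j - 1];
      double diag = D[(size_t)(i - 1) * m + j - 1];
      double best = diag;
      if (up < best) best = up;
      if (left < best) best = left;
      D[(size_t)i * m + j] = best + cost(i, j);
    }
  }

  // traceback
  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  pi.push_back(i + 1); pj.push_back(j + 1);
  while (i > 0 || j > 0) {
    if (i == 0) { --j; }
    else if (j == 0) { --i; }
    else {
      double diag = D[(size_t)(i - 1) * m + j - 1];
      double up   = D[(size_t)(i - 1) * m + j];
      double left = D[(size_t)i * m + j - 1];
      if (diag <= up && diag <= left) { --i; --j; }
      else if (up <= left) { --i; }
      else { --j; }
    }
    pi.push_back(i + 1); pj.push_back(j + 1);
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());

  return List::create(_["distance"] = D[(size_t)n * m - 1],
                      _["index1"] = IntegerVector(pi.begin(), pi.end()),
                      _["index2"] = IntegerVector(pj.begin(), pj.end()));
}

// Single-pass IIR filter, direct form II transposed, with initial state zi
// (length max(length(a), length(b)) - 1). Coefficients must be normalized so
// that a[0] == 1 and padded to a common length.
// [[Rcpp::export]]
NumericVector iir_filter_core(NumericVector b, NumericVector a,
                              NumericVector x, NumericVector zi) {
  const int nf = b.size();
  if (a.size() != nf) stop("a and b must be padded to the same length");
  if (zi.size() != nf - 1) stop("zi must have length length(b) - 1");
  std::vector<double> z(zi.begin(), zi.end());
  const int n = x.size();
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + (nf > 1 ? z[0] : 0.0);
    for (int k = 0; k < nf - 2; ++k)
      z[k] = b[k + 1] * xi + z[k + 1] - a[k + 1] * yi;
    if (nf > 1)
      z[nf - 2] = b[nf - 1] * xi - a[nf - 1] * yi;
    y[i] = yi;
  }
  return y;
}
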