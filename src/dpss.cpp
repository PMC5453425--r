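// Discrete prolate spheroidal sequences via the canonical symmetric
// tridiagonal matrix (diag ((N-1-2t)/2)^2 cos(2*pi*w), off-diag
// t(N-t)/2), solved with LAPACK's tridiagonal bisection + inverse
// iteration for the top k eigenpairs.
#include <Rcpp.h>
#include <R_ext/Lapack.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_dpss_eigvec")]]
NumericMatrix cpp_dpss_eigvec(int n, double w, int k) {
  std::vector<double> d(n), e(n - 1);
  for (int t = 0; t < n; ++t) {
    double a = (n - 1 - 2.0 * t) / 2.0;
    d[t] = a * a * std::cos(2.0 * M_PI * w);
  }
  for (int t = 1; t < n; ++t) e[t - 1] = t * (n - t) / 2.0;

  int il = n - k + 1, iu = n, m = 0, nsplit = 0, info = 0;
  double vl = 0, vu = 0, abstol = 0;
  std::vector<double> wvals(n);
  std::vector<int> iblock(n), isplit(n);
  std::vector<double> work(4 * n);
  std::vector<int> iwork(3 * n);
  F77_CALL(dstebz)("I", "B", &n, &vl, &vu, &il, &iu, &abstol, d.data(),
                   e.data(), &m, &nsplit, wvals.data(), iblock.data(),
                   isplit.data(), work.data(), iwork.data(), &info
                   FCONE FCONE);
  if (info != 0 || m != k) stop("dstebz failed (info = %d)", info);

  NumericMatrix z(n, k);
  std::vector<double> work2(5 * n);
  std::vector<int> iwork2(n), ifail(k);
  F77_CALL(dstein)(&n, d.data(), e.data(), &m, wvals.data(), iblock.data(),
                   isplit.data(), z.begin(), &n, work2.data(),
                   iwork2.data(), ifail.data(), &info);
  if (info != 0) stop("dstein failed (info = %d)", info);

  // eigenvalues ascending from dstebz: reorder columns descending
  NumericMatrix out(n, k);
  for (int j = 0; j < k; ++j)
    std::copy(&z(0, k - 1 - j), &z(0, k - 1 - j) + n, &out(0, j));
  return out;
}
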