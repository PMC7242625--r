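#include <Rcpp.h>
#include <R_ext/Lapack.h>
#include <vector>
using namespace Rcpp;

// Eigenvectors of the m smallest eigenvalues of a symmetric matrix,
// via LAPACK dsyevr with an index range (much cheaper than a full
// decomposition when m << n). Eigenvalues returned in ascending order.
// [[Rcpp::export(name = ".eig_smallest_cpp")]]
List eig_smallest_cpp(NumericMatrix A, int m) {
  int n = A.nrow();
  if (A.ncol() != n) stop("matrix must be square");
  if (m < 1 || m > n) stop("m must be in 1..n");

  std::vector<double> a(A.begin(), A.end()); // dsyevr destroys its input
  char jobz = 'V', range = 'I', uplo = 'L';
  double vl = 0.0, vu = 0.0, abstol = 0.0;
  int il = 1, iu = m, found = 0, info = 0;
  NumericVector w(n);
  NumericMatrix z(n, m);
  std::vector<int> isuppz(2 * (size_t)m);

  int lwork = -1, liwork = -1;
  double wkopt;
  int iwkopt;
  F77_CALL(dsyevr)(&jobz, &range, &uplo, &n, a.data(), &n, &vl, &vu,
                   &il, &iu, &abstol, &found, REAL(w), REAL(z), &n,
                   isuppz.data(), &wkopt, &lwork, &iwkopt, &liwork,
                   &info FCONE FCONE FCONE);
  if (info != 0) stop("dsyevr workspace query failed");
  lwork = (int)wkopt;
  liwork = iwkopt;
  std::vector<double> work((size_t)lwork);
  std::vector<int> iwork((size_t)liwork);
  F77_CALL(dsyevr)(&jobz, &range, &uplo, &n, a.data(), &n, &vl, &vu,
                   &il, &iu, &abstol, &found, REAL(w), REAL(z), &n,
                   isuppz.data(), work.data(), &lwork, iwork.data(), &liwork,
                   &info FCONE FCONE FCONE);
  if (info != 0) stop("dsyevr failed to converge");

  return List::create(_["values"] = NumericVector(w.begin(), w.begin() + m),
                      _["vectors"] = z);
}
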