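// Partial dense symmetric eigendecomposition via LAPACK dsyevr.
// Used for the generalized Laplace-Beltrami eigenproblem after the
// diagonal-mass similarity transform; returns the smallest k eigenpairs.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/Lapack.h>
#ifndef FCONE
#define FCONE
#endif
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".eigs_sym_smallest")]]
List eigs_sym_smallest(NumericMatrix A, int k, bool vectors) {
  int n = A.nrow();
  if (A.ncol() != n) stop("matrix must be square");
  if (k < 1 || k > n) stop("k out of range");

  // dsyevr destroys its input; work on a copy
  std::vector<double> a(A.begin(), A.end());

  char jobz = vectors ? 'V' : 'N';
  char range = (k == n) ? 'A' : 'I';
  char uplo = 'L';
  double vl = 0.0, vu = 0.0;
  int il = 1, iu = k;
  double abstol = 0.0;  // default: safe tolerance
  int m_found = 0;
  std::vector<double> w(n);
  int ldz = n;
  NumericMatrix Z(vectors ? n : 1, vectors ? k : 1);
  std::vector<int> isuppz(2 * (size_t)k + 2);
  int lwork = -1, liwork = -1, info = 0;
  double wkopt = 0.0;
  int iwkopt = 0;

  F77_CALL(dsyevr)(&jobz, &range, &uplo, &n, a.data(), &n, &vl, &vu,
                   &il, &iu, &abstol, &m_found, w.data(), Z.begin(), &ldz,
                   isuppz.data(), &wkopt, &lwork, &iwkopt, &liwork,
                   &info FCONE FCONE FCONE);
  if (info != 0) stop("dsyevr workspace query failed (info=%d)", info);
  lwork = (int)wkopt;
  liwork = iwkopt;
  std::vector<double> work((size_t)lwork);
  std::vector<int> iwork((size_t)liwork);

  F77_CALL(dsyevr)(&jobz, &range, &uplo, &n, a.data(), &n, &vl, &vu,
                   &il, &iu, &abstol, &m_found, w.data(), Z.begin(), &ldz,
                   isuppz.data(), work.data(), &lwork, iwork.data(), &liwork,
                   &info FCONE FCONE FCONE);
  if (info != 0) stop("dsyevr failed (info=%d)", info);
  if (m_found < k) stop("dsyevr found only %d of %d eigenvalues", m_found, k);

  NumericVector values(w.begin(), w.begin() + k);
  if (vectors)
    return List::create(_["values"] = values, _["vectors"] = Z);
  return List::create(_["values"] = values);
}
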