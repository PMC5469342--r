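/* Discrete prolate spheroidal sequences (Slepian tapers).
 *
 * The k most band-concentrated length-n sequences at half-bandwidth W are
 * the top-k eigenvectors of a symmetric tridiagonal matrix
 *   diag_i    = ((n-1-2i)/2)^2 cos(2*pi*W),   i = 0..n-1
 *   offdiag_i = i (n-i) / 2,                  i = 1..n-1
 * (the operator that commutes with the time/band concentration problem).
 * We only need the eigenvectors, so LAPACK's tridiagonal solver dstevr
 * does the whole job in O(n k) memory without forming a dense matrix.
 */
#define USE_FC_LEN_T
#include <Rconfig.h>
#include <R.h>
#include <Rinternals.h>
#include <R_ext/BLAS.h>
#include <R_ext/RS.h>

void F77_NAME(dstevr)(const char *jobz, const char *range, const int *n,
                      double *d, double *e, const double *vl, const double *vu,
                      const int *il, const int *iu, const double *abstol,
                      int *m, double *w, double *z, const int *ldz,
                      int *isuppz, double *work, const int *lwork,
                      int *iwork, const int *liwork, int *info FCLEN FCLEN);

/* Top-k eigenpairs of the symmetric tridiagonal matrix (d, e).
 * Returns list(values, vectors) with eigenvalues ascending. */
SEXP C_tridiag_topk(SEXP d_, SEXP e_, SEXP k_)
{
    int n = LENGTH(d_), k = asInteger(k_);
    if (k < 1 || k > n) error("k must be in [1, n]");
    SEXP d = PROTECT(duplicate(d_));
    SEXP e = PROTECT(duplicate(e_));
    int il = n - k + 1, iu = n, m = 0, info = 0;
    double vl = 0.0, vu = 0.0, abstol = 0.0;
    SEXP w = PROTECT(allocVector(REALSXP, n));
    SEXP z = PROTECT(allocMatrix(REALSXP, n, k));
    int *isuppz = (int *) R_alloc(2 * (size_t) k, sizeof(int));
    int lwork = 20 * n, liwork = 10 * n;
    double *work = (double *) R_alloc((size_t) lwork, sizeof(double));
    int *iwork = (int *) R_alloc((size_t) liwork, sizeof(int));

    F77_CALL(dstevr)("V", "I", &n, REAL(d), REAL(e), &vl, &vu, &il, &iu,
                     &abstol, &m, REAL(w), REAL(z), &n, isuppz, work, &lwork,
                     iwork, &liwork, &info FCONE FCONE);
    if (info != 0) error("LAPACK dstevr failed (info = %d)", info);
    if (m != k) error("dstevr returned %d of %d requested eigenpairs", m, k);

    SEXP vals = PROTECT(allocVector(REALSXP, k));
    for (int j = 0; j < k; j++) REAL(vals)[j] = REAL(w)[j];
    SEXP out = PROTECT(allocVector(VECSXP, 2));
    SET_VECTOR_ELT(out, 0, vals);
    SET_VECTOR_ELT(out, 1, z);
    SEXP nm = PROTECT(allocVector(STRSXP, 2));
    SET_STRING_ELT(nm, 0, mkChar("values"));
    SET_STRING_ELT(nm, 1, mkChar("vectors"));
    setAttrib(out, R_NamesSymbol, nm);
    UNPROTECT(7);
    return out;
}
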