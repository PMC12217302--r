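#include <Rcpp.h>
using namespace Rcpp;

// Selected inverse (Takahashi equations) of a sparse SPD matrix C = L L'
// given its simplicial Cholesky factor. Computes Z = C^{-1} restricted to
// the sparsity pattern of L (lower triangle, CSC).
//
// Pedigree mixed-model factors end in an (almost) dense trailing block;
// the recursion there is cubic with a poor constant. The caller therefore
// supplies the trailing block of C^{-1} (columns >= jcut, 1-based),
// computed densely as (L[T,T] L[T,T]')^{-1}: since L^{-1} is block lower
// triangular, C^{-1}[T,T] depends on L[T,T] only. Those values are
// spliced into the pattern first; the sparse recursion then only runs
// for the leading columns, looking entries up by binary search. The
// clique structure of the filled graph guarantees every entry the
// recursion needs lies on the pattern.

static inline double z_lookup(const IntegerVector& Lp, const IntegerVector& Li,
                              const std::vector<double>& Zx,
                              const NumericMatrix& zdense, int off,
                              int a, int b) {
  if (b >= off) return zdense(a - off, b - off);   // both in the dense tail
  int lo = Lp[b], hi = Lp[b + 1] - 1;
  while (lo <= hi) {
    int mid = (lo + hi) / 2;
    int r = Li[mid];
    if (r == a) return Zx[mid];
    if (r < a) lo = mid + 1; else hi = mid - 1;
  }
  return 0.0;
}

// [[Rcpp::export]]
NumericVector takahashi_cpp(IntegerVector Lp, IntegerVector Li,
                            NumericVector Lx, int n, int jcut,
                            NumericMatrix zdense) {
  std::vector<double> Zx(Lx.size(), 0.0);
  // splice in the dense trailing block (columns jcut..n, 1-based)
  int off = jcut - 1;           // 0-based first dense column
  for (int j = off; j < n; ++j) {
    for (int a = Lp[j]; a < Lp[j + 1]; ++a) {
      int i = Li[a];
      Zx[a] = zdense(i - off, j - off);
    }
  }
  for (int j = off - 1; j >= 0; --j) {
    int start = Lp[j], end = Lp[j + 1];
    double ljj = Lx[start];     // diagonal is the first row in the column
    double dj = ljj * ljj;
    for (int a = end - 1; a >= start + 1; --a) {
      int i = Li[a];
      double acc = 0.0;
      for (int b = start + 1; b < end; ++b) {
        int k = Li[b];
        double lkj = Lx[b] / ljj;
        double z = (k >= i) ? z_lookup(Lp, Li, Zx, zdense, off, k, i)
                            : z_lookup(Lp, Li, Zx, zdense, off, i, k);
        acc += lkj * z;
      }
      Zx[a] = -acc;
    }
    double acc = 1.0 / dj;
    for (int b = start + 1; b < end; ++b) {
      double lkj = Lx[b] / ljj;
      acc -= lkj * Zx[b];
    }
    Zx[start] = acc;
  }
  return NumericVector(Zx.begin(), Zx.end());
}
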