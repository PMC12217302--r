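#include <Rcpp.h>
using namespace Rcpp;

// Pairwise additive relationships from the pedigree recursion A = T D T'.
// For each requested pair (x, y) the rows T[x,] and T[y,] (genome-source
// weights over all nodes) are obtained by pushing weight down from the
// node to its parents; a(x, y) = sum_k T[x,k] * T[y,k] * d[k].
//
// Weights are accumulated in epoch-stamped dense buffers so each query
// costs O(ancestors of x and y), not O(n).

static void t_row(const IntegerVector& dam, const IntegerVector& sire,
                  const NumericVector& c1, const NumericVector& c2,
                  int x, std::vector<double>& val, std::vector<int>& stamp,
                  std::vector<int>& touched, int epoch) {
  touched.clear();
  val[x - 1] = 1.0; stamp[x - 1] = epoch; touched.push_back(x);
  // descending index traversal: parents precede children, so processing
  // ids in decreasing order visits every touched node after all weight
  // has arrived at it
  for (int k = x; k >= 1; --k) {
    if (stamp[k - 1] != epoch) continue;
    double w = val[k - 1];
    if (w == 0.0) continue;
    int p1 = dam[k - 1], p2 = sire[k - 1];
    if (p1 > 0) {
      if (stamp[p1 - 1] != epoch) { stamp[p1 - 1] = epoch; val[p1 - 1] = 0.0; touched.push_back(p1); }
      val[p1 - 1] += w * c1[k - 1];
    }
    if (p2 > 0) {
      if (stamp[p2 - 1] != epoch) { stamp[p2 - 1] = epoch; val[p2 - 1] = 0.0; touched.push_back(p2); }
      val[p2 - 1] += w * c2[k - 1];
    }
  }
}

// [[Rcpp::export]]
NumericVector rel_pairs_cpp(IntegerVector dam, IntegerVector sire,
                            NumericVector c1, NumericVector c2,
                            NumericVector d,
                            IntegerVector xs, IntegerVector ys) {
  int n = dam.size(), m = xs.size();
  if (ys.size() != m) stop("xs and ys must have equal length");
  NumericVector out(m);
  std::vector<double> vx(n), vy(n);
  std::vector<int> sx(n, 0), sy(n, 0), tx, ty;
  int epoch = 0;
  for (int q = 0; q < m; ++q) {
    int x = xs[q], y = ys[q];
    if (x < 1 || x > n || y < 1 || y > n) stop("node id out of range");
    ++epoch;
    t_row(dam, sire, c1, c2, x, vx, sx, tx, epoch);
    t_row(dam, sire, c1, c2, y, vy, sy, ty, epoch);
    double acc = 0.0;
    // iterate over the smaller support
    if (tx.size() <= ty.size()) {
      for (int k : tx) if (sy[k - 1] == epoch) acc += vx[k - 1] * vy[k - 1] * d[k - 1];
    } else {
      for (int k : ty) if (sx[k - 1] == epoch) acc += vx[k - 1] * vy[k - 1] * d[k - 1];
    }
    out[q] = acc;
  }
  return out;
}
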