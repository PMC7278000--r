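#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// 1-D weighted CART regression tree.
//
// Nodes are stored row-wise in a flat matrix:
//   col 0: left child row (1-based) or NA for a leaf
//   col 1: right child row (1-based) or NA for a leaf
//   col 2: split threshold (x <= threshold goes left) or NA for a leaf
//   col 3: fitted value (weighted mean of targets in the node)
//
// Split search: candidate thresholds are midpoints between consecutive
// distinct sorted x values; the split minimising total weighted SSE is
// chosen, ties broken by the lowest threshold. A node is not split when
// depth == max_depth, it holds < 2 examples, all x are equal, or no split
// reduces the weighted SSE.

namespace {

struct Builder {
  const std::vector<double>& x;  // sorted
  const std::vector<double>& y;  // aligned with x
  const std::vector<double>& w;
  int max_depth;
  std::vector<double> left, right, thr, val;

  Builder(const std::vector<double>& x_, const std::vector<double>& y_,
          const std::vector<double>& w_, int max_depth_)
      : x(x_), y(y_), w(w_), max_depth(max_depth_) {}

  int new_node(double value) {
    left.push_back(NA_REAL);
    right.push_back(NA_REAL);
    thr.push_back(NA_REAL);
    val.push_back(value);
    return (int)val.size() - 1;
  }

  // builds subtree over sorted index range [lo, hi); returns node row (0-based)
  int build(int lo, int hi, int depth) {
    double sw = 0.0, swy = 0.0, swy2 = 0.0;
    for (int i = lo; i < hi; ++i) {
      sw += w[i];
      swy += w[i] * y[i];
      swy2 += w[i] * y[i] * y[i];
    }
    double mean = (sw > 0.0) ? swy / sw : 0.0;
    int node = new_node(mean);
    int n = hi - lo;
    if (depth >= max_depth || n < 2 || x[hi - 1] <= x[lo]) return node;

    double sse_total = swy2 - (sw > 0.0 ? swy * swy / sw : 0.0);
    double best_sse = R_PosInf;
    int best_i = -1;  // split after position best_i (left = [lo, best_i])

    double lw = 0.0, lwy = 0.0, lwy2 = 0.0;
    for (int i = lo; i < hi - 1; ++i) {
      lw += w[i];
      lwy += w[i] * y[i];
      lwy2 += w[i] * y[i] * y[i];
      if (x[i + 1] <= x[i]) continue;  // not a boundary between distinct x
      double rw = sw - lw, rwy = swy - lwy, rwy2 = swy2 - lwy2;
      double sse_l = lwy2 - (lw > 0.0 ? lwy * lwy / lw : 0.0);
      double sse_r = rwy2 - (rw > 0.0 ? rwy * rwy / rw : 0.0);
      double s = sse_l + sse_r;
      if (s < best_sse - 1e-12) {  // strict improvement => lowest threshold wins ties
        best_sse = s;
        best_i = i;
      }
    }
    if (best_i < 0 || best_sse >= sse_total - 1e-10 * (1.0 + std::abs(sse_total)))
      return node;

    double threshold = 0.5 * (x[best_i] + x[best_i + 1]);
    int l = build(lo, best_i + 1, depth + 1);
    int r = build(best_i + 1, hi, depth + 1);
    left[node] = l + 1;   // 1-based for R
    right[node] = r + 1;
    thr[node] = threshold;
    return node;
  }
};

}  // namespace

// [[Rcpp::export(name = ".tree_fit_cpp")]]
NumericMatrix tree_fit_cpp(NumericVector x, NumericVector y, NumericVector w,
                           int max_depth) {
  int n = x.size();
  if (n < 1) stop("empty training data");
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return x[a] < x[b]; });
  std::vector<double> xs(n), ys(n), ws(n);
  for (int i = 0; i < n; ++i) {
    xs[i] = x[ord[i]];
    ys[i] = y[ord[i]];
    ws[i] = w[ord[i]];
  }
  Builder b(xs, ys, ws, max_depth);
  b.build(0, n, 0);
  int m = (int)b.val.size();
  NumericMatrix out(m, 4);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = b.left[i];
    out(i, 1) = b.right[i];
    out(i, 2) = b.thr[i];
    out(i, 3) = b.val[i];
  }
  colnames(out) = CharacterVector::create("left", "right", "threshold", "value");
  return out;
}

// [[Rcpp::export(name = ".tree_predict_cpp")]]
NumericVector tree_predict_cpp(NumericMatrix tree, NumericVector x) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (!NumericVector::is_na(tree(node, 2))) {
      node = (x[i] <= tree(node, 2)) ? (int)tree(node, 0) - 1
                                     : (int)tree(node, 1) - 1;
    }
    out[i] = tree(node, 3);
  }
  return out;
}
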