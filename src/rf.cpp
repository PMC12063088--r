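#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Minimal probability random forest for binary outcomes: bootstrap samples,
// mtry random candidate features per node, exhaustive Gini split search,
// leaves store class-1 proportions. Uses R's RNG, so set.seed() in R makes
// forests reproducible. Present because no forest package is available in
// the offline runtime; interface matches the family-adapter contract.

struct Tree {
  std::vector<int> feature;   // -1 for leaf
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<double> prob;
};

static int grow(const NumericMatrix& X, const NumericVector& y,
                std::vector<int>& idx, int lo, int hi, int mtry,
                int min_node, Tree& tree) {
  int node = tree.feature.size();
  tree.feature.push_back(-1); tree.thr.push_back(0.0);
  tree.left.push_back(-1); tree.right.push_back(-1);
  int n = hi - lo;
  double n1 = 0.0;
  for (int k = lo; k < hi; ++k) n1 += y[idx[k]];
  tree.prob.push_back(n1 / n);
  if (n < 2 * min_node || n1 == 0.0 || n1 == n) return node;

  int p = X.ncol();
  // sample mtry distinct features (partial Fisher-Yates on a scratch vector)
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) {
    int k = j + (int)(unif_rand() * (p - j));
    if (k >= p) k = p - 1;
    std::swap(feats[j], feats[k]);
  }
  double best_gain = 0.0, best_thr = 0.0;
  int best_feat = -1;
  double gini_parent = 2.0 * (n1 / n) * (1.0 - n1 / n);
  std::vector<std::pair<double, int> > vals(n);
  for (int j = 0; j < m; ++j) {
    int f = feats[j];
    for (int k = 0; k < n; ++k)
      vals[k] = std::make_pair(X(idx[lo + k], f), idx[lo + k]);
    std::sort(vals.begin(), vals.end());
    double left1 = 0.0;
    for (int k = 0; k < n - 1; ++k) {
      left1 += y[vals[k].second];
      if (vals[k].first == vals[k + 1].first) continue;
      int nl = k + 1, nr = n - nl;
      if (nl < min_node || nr < min_node) continue;
      double pl = left1 / nl, pr = (n1 - left1) / nr;
      double gini = (nl * 2.0 * pl * (1 - pl) + nr * 2.0 * pr * (1 - pr)) / n;
      double gain = gini_parent - gini;
      if (gain > best_gain + 1e-12) {
        best_gain = gain; best_feat = f;
        best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
      }
    }
  }
  if (best_feat < 0) return node;
  // partition idx[lo, hi) in place
  int mid = lo;
  for (int k = lo; k < hi; ++k)
    if (X(idx[k], best_feat) <= best_thr) std::swap(idx[k], idx[mid++]);
  if (mid == lo || mid == hi) return node;
  tree.feature[node] = best_feat;
  tree.thr[node] = best_thr;
  tree.left[node] = grow(X, y, idx, lo, mid, mtry, min_node, tree);
  tree.right[node] = grow(X, y, idx, mid, hi, mtry, min_node, tree);
  return node;
}

// [[Rcpp::export]]
List cpp_rf_fit(NumericMatrix X, NumericVector y, int ntree, int mtry,
                int min_node) {
  int n = X.nrow();
  List forest(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * n);
      if (k >= n) k = n - 1;
      idx[i] = k;
    }
    Tree tree;
    grow(X, y, idx, 0, n, mtry, min_node, tree);
    int nn = tree.feature.size();
    NumericMatrix tm(nn, 5);
    for (int k = 0; k < nn; ++k) {
      tm(k, 0) = tree.feature[k]; tm(k, 1) = tree.thr[k];
      tm(k, 2) = tree.left[k]; tm(k, 3) = tree.right[k];
      tm(k, 4) = tree.prob[k];
    }
    forest[t] = tm;
  }
  return forest;
}

// [[Rcpp::export]]
NumericVector cpp_rf_predict(List forest, NumericMatrix X) {
  int n = X.nrow(), T = forest.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tm = forest[t];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (tm(node, 0) >= 0) {
        int f = (int)tm(node, 0);
        node = (X(i, f) <= tm(node, 1)) ? (int)tm(node, 2) : (int)tm(node, 3);
      }
      out[i] += tm(node, 4);
    }
  }
  return out / T;
}
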