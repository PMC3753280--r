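// Compact classification random forest (CART trees, gini splits, bootstrap
// bagging, per-split feature subsampling). All randomness flows through R's
// RNG so set.seed() in R makes training fully reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold; // go left if x <= threshold
  int left, right;  // child node indices
  int pred;         // majority class at node (0-based)
};

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y; // 0-based classes
  int nclass, mtry, min_node;
  std::vector<Node> nodes;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int nclass_,
              int mtry_, int min_node_)
      : X(X_), y(y_), nclass(nclass_), mtry(mtry_), min_node(min_node_) {}

  int majority(const std::vector<int>& idx) const {
    std::vector<int> cnt(nclass, 0);
    for (int i : idx) cnt[y[i]]++;
    int best = 0;
    for (int c = 1; c < nclass; ++c)
      if (cnt[c] > cnt[best]) best = c; // ties -> smallest class index
    return best;
  }

  bool pure(const std::vector<int>& idx) const {
    for (size_t k = 1; k < idx.size(); ++k)
      if (y[idx[k]] != y[idx[0]]) return false;
    return true;
  }

  // sample m distinct feature indices from 0..d-1 (partial Fisher-Yates)
  void sample_features(int d, int m, std::vector<int>& out) {
    static thread_local std::vector<int> pool;
    pool.resize(d);
    for (int k = 0; k < d; ++k) pool[k] = k;
    out.clear();
    for (int k = 0; k < m; ++k) {
      int r = k + (int)(R::unif_rand() * (d - k));
      if (r >= d) r = d - 1;
      std::swap(pool[k], pool[r]);
      out.push_back(pool[k]);
    }
  }

  int grow(std::vector<int>& idx) {
    int me = (int)nodes.size();
    nodes.push_back(Node{-1, 0.0, -1, -1, majority(idx)});
    if ((int)idx.size() < 2 * min_node || pure(idx)) return me;

    int d = X.ncol();
    std::vector<int> feats;
    sample_features(d, std::min(mtry, d), feats);

    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;

    std::vector<int> cnt_tot(nclass, 0);
    for (int i : idx) cnt_tot[y[i]]++;
    double n = (double)idx.size();
    double imp_parent = 1.0;
    for (int c = 0; c < nclass; ++c) {
      double p = cnt_tot[c] / n;
      imp_parent -= p * p;
    }

    std::vector<std::pair<double, int> > vals;
    for (int f : feats) {
      vals.clear();
      for (int i : idx) vals.push_back(std::make_pair(X(i, f), y[i]));
      std::sort(vals.begin(), vals.end());
      std::vector<int> cl(nclass, 0);
      int nl = 0;
      for (size_t k = 0; k + 1 < vals.size(); ++k) {
        cl[vals[k].second]++;
        nl++;
        if (vals[k].first == vals[k + 1].first) continue;
        int nr = (int)vals.size() - nl;
        double gl = 1.0, gr = 1.0;
        for (int c = 0; c < nclass; ++c) {
          double pl = (double)cl[c] / nl;
          double pr = (double)(cnt_tot[c] - cl[c]) / nr;
          gl -= pl * pl;
          gr -= pr * pr;
        }
        double gain = imp_parent - (nl * gl + nr * gr) / n;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
        }
      }
    }
    if (best_f < 0) return me;

    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) li.push_back(i);
      else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) return me;
    nodes[me].feature = best_f;
    nodes[me].threshold = best_thr;
    int l = grow(li);
    int r = grow(ri);
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }
};

int predict_tree(const IntegerVector& feat, const NumericVector& thr,
                 const IntegerVector& left, const IntegerVector& right,
                 const IntegerVector& pred, const NumericMatrix& X, int row) {
  int k = 0;
  while (feat[k] >= 0)
    k = (X(row, feat[k]) <= thr[k]) ? left[k] : right[k];
  return pred[k];
}

} // namespace

// [[Rcpp::export]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int nclass, int ntree,
                  int mtry, int min_node) {
  int n = X.nrow();
  List trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int k = 0; k < n; ++k) {
      int r = (int)(R::unif_rand() * n);
      if (r >= n) r = n - 1;
      idx[k] = r;
    }
    TreeBuilder tb(X, y, nclass, mtry, min_node);
    tb.grow(idx);
    int m = (int)tb.nodes.size();
    IntegerVector feat(m), left(m), right(m), pred(m);
    NumericVector thr(m);
    for (int k = 0; k < m; ++k) {
      feat[k] = tb.nodes[k].feature;
      thr[k] = tb.nodes[k].threshold;
      left[k] = tb.nodes[k].left;
      right[k] = tb.nodes[k].right;
      pred[k] = tb.nodes[k].pred;
    }
    trees[t] = List::create(Named("feature") = feat, Named("threshold") = thr,
                            Named("left") = left, Named("right") = right,
                            Named("pred") = pred);
  }
  return trees;
}

// [[Rcpp::export]]
IntegerMatrix rf_votes_cpp(List trees, NumericMatrix X, int nclass) {
  int n = X.nrow(), T = trees.size();
  IntegerMatrix votes(n, nclass);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feat = tr["feature"], left = tr["left"],
                  right = tr["right"], pred = tr["pred"];
    NumericVector thr = tr["threshold"];
    for (int i = 0; i < n; ++i)
      votes(i, predict_tree(feat, thr, left, right, pred, X, i))++;
  }
  return votes;
}
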