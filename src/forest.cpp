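// Native bagged CART classification forest with SER (structure
// expansion/reduction) transfer adaptation. Trees are implemented natively
// because transfer requires routing new samples to leaves, growing subtrees
// at leaves, and bottom-up pruning — operations an off-the-shelf forest does
// not expose. Determinism contract: (data, config, seed) -> identical trees;
// split ties are broken toward the lowest feature index, then the lowest
// threshold.

#include <Rcpp.h>
#include <vector>
#include <random>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;        // -1 for leaf
  std::vector<double> threshold;   // x[feature] <= threshold -> left
  std::vector<int> left, right;
  std::vector<std::vector<double>> counts;  // per-node class distribution basis
};

int new_node(Tree &t, const std::vector<double> &cnt) {
  t.feature.push_back(-1);
  t.threshold.push_back(0.0);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.counts.push_back(cnt);
  return static_cast<int>(t.feature.size()) - 1;
}

std::vector<double> class_counts(const IntegerVector &y, const std::vector<int> &idx,
                                 int n_classes) {
  std::vector<double> cnt(n_classes, 0.0);
  for (int i : idx) cnt[y[i]] += 1.0;
  return cnt;
}

double weighted_child_impurity(const std::vector<double> &lc, double ln,
                               const std::vector<double> &rc, double rn) {
  double sl = 0.0, sr = 0.0;
  for (double v : lc) sl += v * v;
  for (double v : rc) sr += v * v;
  double il = (ln > 0) ? 1.0 - sl / (ln * ln) : 0.0;
  double ir = (rn > 0) ? 1.0 - sr / (rn * rn) : 0.0;
  double n = ln + rn;
  return (ln / n) * il + (rn / n) * ir;
}

struct SplitResult {
  bool found = false;
  int feature = -1;
  double threshold = 0.0;
  double score = 0.0;  // weighted child gini to minimize
};

SplitResult best_split(const NumericMatrix &X, const IntegerVector &y,
                       const std::vector<int> &idx, int n_classes,
                       const std::vector<int> &feats,
                       double parent_impurity) {
  SplitResult best;
  const double eps = 1e-12;
  const size_t n = idx.size();
  std::vector<std::pair<double, int>> vals(n);  // (value, class)
  for (int f : feats) {
    for (size_t i = 0; i < n; ++i) vals[i] = {X(idx[i], f), y[idx[i]]};
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;
    std::vector<double> lc(n_classes, 0.0), rc(n_classes, 0.0);
    for (size_t i = 0; i < n; ++i) rc[vals[i].second] += 1.0;
    for (size_t i = 0; i + 1 < n; ++i) {
      lc[vals[i].second] += 1.0;
      rc[vals[i].second] -= 1.0;
      if (vals[i].first == vals[i + 1].first) continue;
      double score = weighted_child_impurity(lc, static_cast<double>(i + 1),
                                             rc, static_cast<double>(n - i - 1));
      if (score < parent_impurity - eps &&
          (!best.found || score < best.score - eps)) {
        best.found = true;
        best.feature = f;
        best.threshold = 0.5 * (vals[i].first + vals[i + 1].first);
        best.score = score;
      }
    }
  }
  return best;
}

std::vector<int> draw_features(int n_features, int mtry, std::mt19937 &rng) {
  std::vector<int> all(n_features);
  for (int i = 0; i < n_features; ++i) all[i] = i;
  for (int i = 0; i < mtry && i < n_features; ++i) {
    std::uniform_int_distribution<int> u(i, n_features - 1);
    std::swap(all[i], all[u(rng)]);
  }
  all.resize(std::min(mtry, n_features));
  std::sort(all.begin(), all.end());
  return all;
}

// Grow a CART subtree rooted at node `node` of `t` from samples `idx`.
void grow(Tree &t, int node, const NumericMatrix &X, const IntegerVector &y,
          std::vector<int> idx, int n_classes, int mtry, int min_split,
          int depth, int max_depth, std::mt19937 &rng) {
  const std::vector<double> &cnt = t.counts[node];
  double n = 0.0, smax = 0.0, ssum = 0.0;
  for (double v : cnt) { n += v; smax = std::max(smax, v); ssum += v * v; }
  bool pure = (smax == n);
  if (pure || depth >= max_depth || static_cast<int>(idx.size()) < min_split) return;
  double parent_imp = 1.0 - ssum / (n * n);
  std::vector<int> feats = draw_features(X.ncol(), mtry, rng);
  SplitResult sp = best_split(X, y, idx, n_classes, feats, parent_imp);
  if (!sp.found) return;
  std::vector<int> li, ri;
  for (int i : idx) {
    if (X(i, sp.feature) <= sp.threshold) li.push_back(i); else ri.push_back(i);
  }
  if (li.empty() || ri.empty()) return;
  t.feature[node] = sp.feature;
  t.threshold[node] = sp.threshold;
  int l = new_node(t, class_counts(y, li, n_classes));
  int r = new_node(t, class_counts(y, ri, n_classes));
  t.left[node] = l;
  t.right[node] = r;
  grow(t, l, X, y, li, n_classes, mtry, min_split, depth + 1, max_depth, rng);
  grow(t, r, X, y, ri, n_classes, mtry, min_split, depth + 1, max_depth, rng);
}

int route(const Tree &t, const NumericMatrix &X, int row) {
  int node = 0;
  while (t.feature[node] >= 0) {
    node = (X(row, t.feature[node]) <= t.threshold[node]) ? t.left[node] : t.right[node];
  }
  return node;
}

List tree_to_list(const Tree &t, int n_classes) {
  int n = static_cast<int>(t.feature.size());
  IntegerVector feature(n), left(n), right(n);
  NumericVector threshold(n);
  NumericMatrix counts(n, n_classes);
  for (int i = 0; i < n; ++i) {
    feature[i] = t.feature[i];
    threshold[i] = t.threshold[i];
    left[i] = t.left[i];
    right[i] = t.right[i];
    for (int k = 0; k < n_classes; ++k) counts(i, k) = t.counts[i][k];
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right, _["counts"] = counts);
}

Tree tree_from_list(const List &l) {
  Tree t;
  IntegerVector feature = l["feature"], left = l["left"], right = l["right"];
  NumericVector threshold = l["threshold"];
  NumericMatrix counts = l["counts"];
  int n = feature.size(), K = counts.ncol();
  t.feature.assign(feature.begin(), feature.end());
  t.threshold.assign(threshold.begin(), threshold.end());
  t.left.assign(left.begin(), left.end());
  t.right.assign(right.begin(), right.end());
  t.counts.resize(n);
  for (int i = 0; i < n; ++i) {
    t.counts[i].resize(K);
    for (int k = 0; k < K; ++k) t.counts[i][k] = counts(i, k);
  }
  return t;
}

// Recursively prune subtree at `node`; returns target misclassification
// count of the (possibly collapsed) subtree. `tc` holds per-node target
// class counts.
double reduce_node(Tree &t, int node, const std::vector<std::vector<double>> &tc) {
  if (t.feature[node] < 0) {
    // leaf error under the leaf's stored distribution
    int pred = 0;
    for (size_t k = 1; k < t.counts[node].size(); ++k) {
      if (t.counts[node][k] > t.counts[node][pred]) pred = static_cast<int>(k);
    }
    double err = 0.0, tot = 0.0;
    for (size_t k = 0; k < tc[node].size(); ++k) tot += tc[node][k];
    err = tot - tc[node][pred];
    return err;
  }
  double err_sub = reduce_node(t, t.left[node], tc) +
                   reduce_node(t, t.right[node], tc);
  double tot = 0.0;
  for (double v : tc[node]) tot += v;
  if (tot >= 1.0) {
    int mc = 0;
    for (size_t k = 1; k < tc[node].size(); ++k) {
      if (tc[node][k] > tc[node][mc]) mc = static_cast<int>(k);
    }
    double err_col = tot - tc[node][mc];
    if (err_col <= err_sub) {
      t.feature[node] = -1;
      t.left[node] = -1;
      t.right[node] = -1;
      for (size_t k = 0; k < tc[node].size(); ++k) t.counts[node][k] = tc[node][k] + 1.0;
      return err_col;
    }
  }
  return err_sub;
}

void accumulate_target_counts(const Tree &t, const NumericMatrix &X,
                              const IntegerVector &y,
                              std::vector<std::vector<double>> &tc) {
  int K = static_cast<int>(t.counts[0].size());
  tc.assign(t.feature.size(), std::vector<double>(K, 0.0));
  for (int i = 0; i < X.nrow(); ++i) {
    int node = 0;
    tc[node][y[i]] += 1.0;
    while (t.feature[node] >= 0) {
      node = (X(i, t.feature[node]) <= t.threshold[node]) ? t.left[node] : t.right[node];
      tc[node][y[i]] += 1.0;
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int n_classes, int n_trees,
                  int mtry, int min_split, int max_depth, int seed) {
  int n = X.nrow();
  List forest(n_trees);
  for (int tr = 0; tr < n_trees; ++tr) {
    std::mt19937 rng(static_cast<std::uint32_t>(seed) + 7919u * static_cast<std::uint32_t>(tr));
    std::uniform_int_distribution<int> u(0, n - 1);
    std::vector<int> boot(n);
    for (int i = 0; i < n; ++i) boot[i] = u(rng);
    Tree t;
    int root = new_node(t, class_counts(y, boot, n_classes));
    grow(t, root, X, y, boot, n_classes, mtry, min_split, 0, max_depth, rng);
    forest[tr] = tree_to_list(t, n_classes);
  }
  return forest;
}

// [[Rcpp::export]]
NumericMatrix rf_predict_cpp(List forest, NumericMatrix X, int n_classes) {
  int n = X.nrow();
  NumericMatrix out(n, n_classes);
  int n_trees = forest.size();
  for (int tr = 0; tr < n_trees; ++tr) {
    Tree t = tree_from_list(forest[tr]);
    for (int i = 0; i < n; ++i) {
      int leaf = route(t, X, i);
      double tot = 0.0;
      for (double v : t.counts[leaf]) tot += v;
      if (tot <= 0) continue;
      for (int k = 0; k < n_classes; ++k) out(i, k) += t.counts[leaf][k] / tot;
    }
  }
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = 0; k < n_classes; ++k) s += out(i, k);
    if (s > 0) for (int k = 0; k < n_classes; ++k) out(i, k) /= s;
    else for (int k = 0; k < n_classes; ++k) out(i, k) = 1.0 / n_classes;
  }
  return out;
}

// [[Rcpp::export]]
List rf_ser_cpp(List forest, NumericMatrix X, IntegerVector y, int n_classes,
                int mtry, int min_split, int max_depth, int min_leaf_expand,
                int seed) {
  int n_trees = forest.size();
  List out(n_trees);
  int n_unchanged = 0;
  for (int tr = 0; tr < n_trees; ++tr) {
    Tree t = tree_from_list(forest[tr]);
    std::mt19937 rng(static_cast<std::uint32_t>(seed) + 7919u * static_cast<std::uint32_t>(tr));
    size_t nodes_before = t.feature.size();
    // (i) expansion: grow subtrees at leaves holding enough target samples
    std::vector<std::vector<int>> leaf_samples(t.feature.size());
    for (int i = 0; i < X.nrow(); ++i) leaf_samples[route(t, X, i)].push_back(i);
    for (size_t node = 0; node < leaf_samples.size(); ++node) {
      if (t.feature[node] < 0 &&
          static_cast<int>(leaf_samples[node].size()) >= min_leaf_expand) {
        t.counts[node] = class_counts(y, leaf_samples[node], n_classes);
        grow(t, static_cast<int>(node), X, y, leaf_samples[node], n_classes,
             mtry, min_split, 0, max_depth, rng);
      }
    }
    // target counts at every node after expansion
    std::vector<std::vector<double>> tc;
    accumulate_target_counts(t, X, y, tc);
    // re-estimate leaf distributions from target counts (Laplace +1) where
    // target samples reach; leaves unseen by the target keep source counts
    bool touched = t.feature.size() != nodes_before;
    for (size_t node = 0; node < t.feature.size(); ++node) {
      if (t.feature[node] >= 0) continue;
      double tot = 0.0;
      for (double v : tc[node]) tot += v;
      if (tot >= 1.0) {
        touched = true;
        for (int k = 0; k < n_classes; ++k) t.counts[node][k] = tc[node][k] + 1.0;
      }
    }
    // (ii) reduction: bottom-up collapse where target error does not worsen
    reduce_node(t, 0, tc);
    if (!touched) ++n_unchanged;
    out[tr] = tree_to_list(t, n_classes);
  }
  out.attr("n_unchanged") = n_unchanged;
  return out;
}
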