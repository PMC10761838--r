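#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Classification random forest (CART trees, Gini impurity, bootstrap +
// random feature subsets, out-of-bag votes). Trees are grown to purity
// unless min_node stops them; ties in prediction go to the lowest class
// index so results are reproducible across platforms.

namespace {

struct TreeNodes {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // x[feature] <= threshold -> left
  std::vector<int> left, right;
  std::vector<int> pred;         // leaf class (majority, lowest index on tie)
};

int majority_class(const std::vector<int>& counts) {
  int best = 0;
  for (size_t k = 1; k < counts.size(); ++k)
    if (counts[k] > counts[best]) best = (int)k;
  return best;
}

double gini_from_counts(const std::vector<int>& counts, int n) {
  if (n == 0) return 0.0;
  double g = 1.0;
  for (int c : counts) {
    double p = (double)c / n;
    g -= p * p;
  }
  return g;
}

void grow_node(const NumericMatrix& X, const IntegerVector& y, int nclass,
               std::vector<int>& idx_pool, int lo, int hi, TreeNodes& tree,
               int node_id, int mtry, int min_node, std::mt19937& rng,
               std::vector<int>& feat_order) {
  int n = hi - lo;
  std::vector<int> counts(nclass, 0);
  for (int i = lo; i < hi; ++i) counts[y[idx_pool[i]]]++;
  int maj = majority_class(counts);
  bool pure = counts[maj] == n;

  if (pure || n < min_node) {
    tree.feature[node_id] = -1;
    tree.pred[node_id] = maj;
    return;
  }

  double parent_gini = gini_from_counts(counts, n);
  int best_feat = -1;
  double best_thr = 0.0, best_score = parent_gini - 1e-12;

  // random subset of features without replacement
  std::shuffle(feat_order.begin(), feat_order.end(), rng);
  std::vector<std::pair<double, int>> vals(n);
  std::vector<int> lcounts(nclass);

  for (int fi = 0; fi < mtry; ++fi) {
    int f = feat_order[fi];
    for (int i = 0; i < n; ++i) {
      int s = idx_pool[lo + i];
      vals[i] = std::make_pair(X(s, f), y[s]);
    }
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;
    std::fill(lcounts.begin(), lcounts.end(), 0);
    for (int i = 0; i < n - 1; ++i) {
      lcounts[vals[i].second]++;
      if (vals[i].first == vals[i + 1].first) continue;
      int nl = i + 1, nr = n - nl;
      double gl = 1.0, gr = 1.0;
      for (int k = 0; k < nclass; ++k) {
        double pl = (double)lcounts[k] / nl;
        double pr = (double)(counts[k] - lcounts[k]) / nr;
        gl -= pl * pl;
        gr -= pr * pr;
      }
      double score = ((double)nl * gl + (double)nr * gr) / n;
      if (score < best_score) {
        best_score = score;
        best_feat = f;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }

  if (best_feat < 0) { // no impurity-reducing split found
    tree.feature[node_id] = -1;
    tree.pred[node_id] = maj;
    return;
  }

  // partition idx_pool[lo, hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx_pool[i], best_feat) <= best_thr) std::swap(idx_pool[i], idx_pool[mid++]);
  if (mid == lo || mid == hi) { // numeric tie pathology
    tree.feature[node_id] = -1;
    tree.pred[node_id] = maj;
    return;
  }

  int lid = (int)tree.feature.size();
  tree.feature.push_back(0); tree.threshold.push_back(0);
  tree.left.push_back(-1); tree.right.push_back(-1); tree.pred.push_back(-1);
  int rid = (int)tree.feature.size();
  tree.feature.push_back(0); tree.threshold.push_back(0);
  tree.left.push_back(-1); tree.right.push_back(-1); tree.pred.push_back(-1);

  tree.feature[node_id] = best_feat;
  tree.threshold[node_id] = best_thr;
  tree.left[node_id] = lid;
  tree.right[node_id] = rid;

  grow_node(X, y, nclass, idx_pool, lo, mid, tree, lid, mtry, min_node, rng, feat_order);
  grow_node(X, y, nclass, idx_pool, mid, hi, tree, rid, mtry, min_node, rng, feat_order);
}

int tree_predict_one(const TreeNodes& t, const NumericMatrix& X, int row) {
  int node = 0;
  while (t.feature[node] >= 0)
    node = (X(row, t.feature[node]) <= t.threshold[node]) ? t.left[node] : t.right[node];
  return t.pred[node];
}

TreeNodes unpack_tree(const List& tl) {
  TreeNodes t;
  t.feature = as<std::vector<int>>(tl["feature"]);
  t.threshold = as<std::vector<double>>(tl["threshold"]);
  t.left = as<std::vector<int>>(tl["left"]);
  t.right = as<std::vector<int>>(tl["right"]);
  t.pred = as<std::vector<int>>(tl["pred"]);
  return t;
}

} // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int nclass, int ntree,
                int mtry, int min_node, int seed) {
  int n = X.nrow(), p = X.ncol();
  if (mtry > p) mtry = p;
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> boot(0, n - 1);

  List trees(ntree);
  IntegerMatrix oob_votes(n, nclass);

  std::vector<int> feat_order(p);
  for (int j = 0; j < p; ++j) feat_order[j] = j;

  for (int t = 0; t < ntree; ++t) {
    std::vector<int> inbag(n, 0), idx;
    idx.reserve(n);
    for (int i = 0; i < n; ++i) {
      int s = boot(rng);
      inbag[s]++;
      idx.push_back(s);
    }
    TreeNodes tree;
    tree.feature.assign(1, 0); tree.threshold.assign(1, 0);
    tree.left.assign(1, -1); tree.right.assign(1, -1); tree.pred.assign(1, -1);
    grow_node(X, y, nclass, idx, 0, n, tree, 0, mtry, min_node, rng, feat_order);

    for (int i = 0; i < n; ++i)
      if (inbag[i] == 0) oob_votes(i, tree_predict_one(tree, X, i))++;

    trees[t] = List::create(_["feature"] = tree.feature,
                            _["threshold"] = tree.threshold,
                            _["left"] = tree.left, _["right"] = tree.right,
                            _["pred"] = tree.pred);
  }

  int oob_n = 0, oob_wrong = 0;
  IntegerVector oob_pred(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    int best = 0, tot = 0;
    for (int k = 0; k < nclass; ++k) {
      tot += oob_votes(i, k);
      if (oob_votes(i, k) > oob_votes(i, best)) best = k;
    }
    if (tot > 0) {
      oob_pred[i] = best;
      oob_n++;
      if (best != y[i]) oob_wrong++;
    }
  }
  double oob_err = oob_n > 0 ? (double)oob_wrong / oob_n : NA_REAL;

  return List::create(_["trees"] = trees, _["oob_error"] = oob_err,
                      _["oob_pred"] = oob_pred, _["nclass"] = nclass);
}

// [[Rcpp::export]]
IntegerVector rf_predict_cpp(List forest, NumericMatrix X) {
  List trees = forest["trees"];
  int nclass = as<int>(forest["nclass"]);
  int n = X.nrow(), ntree = trees.size();
  std::vector<TreeNodes> unpacked(ntree);
  for (int t = 0; t < ntree; ++t) unpacked[t] = unpack_tree(trees[t]);

  IntegerVector out(n);
  std::vector<int> votes(nclass);
  for (int i = 0; i < n; ++i) {
    std::fill(votes.begin(), votes.end(), 0);
    for (int t = 0; t < ntree; ++t) votes[tree_predict_one(unpacked[t], X, i)]++;
    int best = 0;
    for (int k = 1; k < nclass; ++k)
      if (votes[k] > votes[best]) best = k; // tie -> lowest class index
    out[i] = best;
  }
  return out;
}
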