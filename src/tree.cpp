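#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Greedy variance-reduction regression tree used by the boosted-tree and
// bagged-forest learners. Rows are passed explicitly (0-based, duplicates
// allowed) so bootstrap resampling stays on the R side; mtry features are
// drawn without replacement at every split with an own mt19937 stream so
// fits are reproducible independently of R's RNG state.

struct NodeWork {
  int node_id;
  int depth;
  std::vector<int> rows;
};

// [[Rcpp::export]]
List grow_tree_cpp(NumericMatrix X, NumericVector y, IntegerVector rows,
                   int max_depth, int min_node, int mtry, int seed) {
  const int p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  if (min_node < 1) min_node = 1;

  std::mt19937 rng(static_cast<unsigned int>(seed));

  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // split: x <= threshold goes left
  std::vector<int> left, right;
  std::vector<double> value;     // node mean
  NumericVector gain(p);         // summed SSE reduction per feature

  std::vector<NodeWork> stack;
  {
    NodeWork root;
    root.node_id = 0;
    root.depth = 0;
    root.rows.assign(rows.begin(), rows.end());
    feature.push_back(-1); threshold.push_back(NA_REAL);
    left.push_back(-1); right.push_back(-1); value.push_back(0.0);
    stack.push_back(std::move(root));
  }

  std::vector<int> feat_pool(p);
  for (int j = 0; j < p; ++j) feat_pool[j] = j;

  while (!stack.empty()) {
    NodeWork nw = std::move(stack.back());
    stack.pop_back();
    const std::vector<int> &idx = nw.rows;
    const int n = static_cast<int>(idx.size());

    double sum = 0.0;
    for (int i = 0; i < n; ++i) sum += y[idx[i]];
    const double mean = sum / n;
    value[nw.node_id] = mean;

    if (nw.depth >= max_depth || n < 2 * min_node) continue;

    // sample mtry distinct candidate features (partial Fisher-Yates)
    for (int j = 0; j < mtry; ++j) {
      std::uniform_int_distribution<int> u(j, p - 1);
      std::swap(feat_pool[j], feat_pool[u(rng)]);
    }

    double best_gain = 0.0, best_thr = 0.0;
    int best_feat = -1;
    const double parent_score = sum * sum / n;

    std::vector<std::pair<double, double> > xy(n);
    for (int j = 0; j < mtry; ++j) {
      const int f = feat_pool[j];
      for (int i = 0; i < n; ++i)
        xy[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
      std::sort(xy.begin(), xy.end());
      if (xy[0].first == xy[n - 1].first) continue; // constant in node
      double lsum = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        lsum += xy[i].second;
        if (xy[i].first == xy[i + 1].first) continue;
        const int nl = i + 1, nr = n - nl;
        if (nl < min_node || nr < min_node) continue;
        const double rsum = sum - lsum;
        const double g = lsum * lsum / nl + rsum * rsum / nr - parent_score;
        if (g > best_gain) {
          best_gain = g;
          best_feat = f;
          best_thr = 0.5 * (xy[i].first + xy[i + 1].first);
        }
      }
    }

    if (best_feat < 0) continue;
    gain[best_feat] += best_gain;

    NodeWork lw, rw;
    lw.depth = rw.depth = nw.depth + 1;
    for (int i = 0; i < n; ++i) {
      if (X(idx[i], best_feat) <= best_thr) lw.rows.push_back(idx[i]);
      else rw.rows.push_back(idx[i]);
    }
    const int lid = static_cast<int>(feature.size());
    const int rid = lid + 1;
    feature.push_back(-1); threshold.push_back(NA_REAL);
    left.push_back(-1); right.push_back(-1); value.push_back(0.0);
    feature.push_back(-1); threshold.push_back(NA_REAL);
    left.push_back(-1); right.push_back(-1); value.push_back(0.0);

    feature[nw.node_id] = best_feat;
    threshold[nw.node_id] = best_thr;
    left[nw.node_id] = lid;
    right[nw.node_id] = rid;

    lw.node_id = lid;
    rw.node_id = rid;
    stack.push_back(std::move(lw));
    stack.push_back(std::move(rw));
  }

  return List::create(
      _["feature"] = wrap(feature), _["threshold"] = wrap(threshold),
      _["left"] = wrap(left), _["right"] = wrap(right),
      _["value"] = wrap(value), _["gain"] = gain);
}

// [[Rcpp::export]]
NumericVector predict_tree_cpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"];
  IntegerVector right = tree["right"];
  NumericVector value = tree["value"];

  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    }
    out[i] = value[node];
  }
  return out;
}

// Sum of weighted tree predictions; trees is a list of grow_tree_cpp fits.
// [[Rcpp::export]]
NumericVector predict_ensemble_cpp(List trees, NumericVector weights,
                                   NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n);
  const int m = trees.size();
  for (int t = 0; t < m; ++t) {
    List tree = trees[t];
    NumericVector pred = predict_tree_cpp(tree, X);
    const double w = weights[t];
    for (int i = 0; i < n; ++i) out[i] += w * pred[i];
  }
  return out;
}
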