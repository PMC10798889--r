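// A compact classification random forest: bootstrap sampling, CART trees with
// gini splits over mtry randomly drawn features, grown to purity, majority
// vote per leaf. Class probabilities are tree-vote fractions. A dedicated
// RNG (seeded from R) keeps forests bit-reproducible without touching the
// R RNG stream.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

struct TreeNodes {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // split: x <= threshold goes left
  std::vector<int> left, right;  // child node indices
  std::vector<int> klass;        // leaf majority class (0-based)
};

struct Task { int node; std::vector<int> idx; };

static int majority(const std::vector<int>& idx, const IntegerVector& y, int K) {
  std::vector<int> cnt(K, 0);
  for (int i : idx) cnt[y[i]]++;
  return (int)(std::max_element(cnt.begin(), cnt.end()) - cnt.begin());
}

static bool pure(const std::vector<int>& idx, const IntegerVector& y) {
  for (size_t i = 1; i < idx.size(); ++i)
    if (y[idx[i]] != y[idx[0]]) return false;
  return true;
}

// [[Rcpp::export(name = ".rf_train")]]
List rf_train(const NumericMatrix& X, const IntegerVector& y, int K,
              int ntree, int mtry, int min_node, double seed) {
  const int n = X.nrow(), p = X.ncol();
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_int_distribution<int> pick_n(0, n - 1);
  List trees(ntree);
  std::vector<int> feat_pool(p);
  for (int j = 0; j < p; ++j) feat_pool[j] = j;

  for (int t = 0; t < ntree; ++t) {
    // bootstrap sample
    std::vector<int> boot(n);
    for (int i = 0; i < n; ++i) boot[i] = pick_n(rng);
    TreeNodes tr;
    std::vector<Task> stack;
    auto new_node = [&]() {
      tr.feature.push_back(-1); tr.threshold.push_back(0.0);
      tr.left.push_back(-1); tr.right.push_back(-1); tr.klass.push_back(0);
      return (int)tr.feature.size() - 1;
    };
    int root = new_node();
    stack.push_back({root, boot});
    while (!stack.empty()) {
      Task task = std::move(stack.back());
      stack.pop_back();
      std::vector<int>& idx = task.idx;
      int node = task.node;
      int m = (int)idx.size();
      if (m < 2 * min_node || m < 2 || pure(idx, y)) {
        tr.klass[node] = majority(idx, y, K);
        continue;
      }
      // class counts at node
      std::vector<double> total(K, 0.0);
      for (int i : idx) total[y[i]] += 1.0;
      // draw mtry features without replacement (partial Fisher-Yates)
      for (int j = 0; j < mtry; ++j) {
        std::uniform_int_distribution<int> pick(j, p - 1);
        std::swap(feat_pool[j], feat_pool[pick(rng)]);
      }
      double best_gain = 0.0, best_thr = 0.0;
      int best_feat = -1;
      double parent_imp = 0.0;
      for (int c = 0; c < K; ++c) parent_imp += total[c] * total[c];
      parent_imp = 1.0 - parent_imp / ((double)m * m);
      std::vector<std::pair<double,int>> vals(m);
      for (int fj = 0; fj < mtry; ++fj) {
        int f = feat_pool[fj];
        for (int i = 0; i < m; ++i) vals[i] = {X(idx[i], f), y[idx[i]]};
        std::sort(vals.begin(), vals.end());
        if (vals.front().first == vals.back().first) continue;
        std::vector<double> lc(K, 0.0);
        double nl = 0.0;
        for (int i = 0; i < m - 1; ++i) {
          lc[vals[i].second] += 1.0;
          nl += 1.0;
          if (vals[i].first == vals[i + 1].first) continue;
          double nr = m - nl;
          double sl = 0.0, sr = 0.0;
          for (int c = 0; c < K; ++c) {
            sl += lc[c] * lc[c];
            double rc = total[c] - lc[c];
            sr += rc * rc;
          }
          double child_imp = (nl - sl / nl + nr - sr / nr) / m;
          double gain = parent_imp - child_imp;
          if (gain > best_gain + 1e-12) {
            best_gain = gain;
            best_feat = f;
            best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
          }
        }
      }
      if (best_feat < 0) {
        tr.klass[node] = majority(idx, y, K);
        continue;
      }
      std::vector<int> li, ri;
      for (int i : idx) {
        if (X(i, best_feat) <= best_thr) li.push_back(i); else ri.push_back(i);
      }
      if (li.empty() || ri.empty()) {
        tr.klass[node] = majority(idx, y, K);
        continue;
      }
      int ln = new_node(), rn = new_node();
      tr.feature[node] = best_feat;
      tr.threshold[node] = best_thr;
      tr.left[node] = ln;
      tr.right[node] = rn;
      stack.push_back({ln, std::move(li)});
      stack.push_back({rn, std::move(ri)});
    }
    trees[t] = List::create(
      Named("feature") = IntegerVector(tr.feature.begin(), tr.feature.end()),
      Named("threshold") = NumericVector(tr.threshold.begin(), tr.threshold.end()),
      Named("left") = IntegerVector(tr.left.begin(), tr.left.end()),
      Named("right") = IntegerVector(tr.right.begin(), tr.right.end()),
      Named("klass") = IntegerVector(tr.klass.begin(), tr.klass.end()));
  }
  return trees;
}

// [[Rcpp::export(name = ".rf_votes")]]
NumericMatrix rf_votes(const List& trees, const NumericMatrix& X, int K) {
  const int n = X.nrow(), ntree = trees.size();
  NumericMatrix votes(n, K);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"], klass = tr["klass"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0) {
        node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
      }
      votes(i, klass[node]) += 1.0;
    }
  }
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < K; ++c) votes(i, c) /= ntree;
  return votes;
}
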