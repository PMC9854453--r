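#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Minimal regression-tree backend for the in-package random-forest and
// boosted-tree learners: exhaustive split search under the variance
// criterion, optional per-node feature subsampling (mtry), deterministic
// via a caller-supplied seed (xorshift64; R never sees this stream).

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  // uniform integer in [0, n)
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

struct Node {
  int feature = -1;          // -1 marks a leaf
  double threshold = 0.0;    // go left iff x <= threshold
  int left = -1, right = -1;
  double value = 0.0;        // node mean of y
};

struct Builder {
  const NumericMatrix& X;
  const NumericVector& y;
  int max_depth, min_node, mtry;
  XorShift rng;
  std::vector<Node> nodes;

  Builder(const NumericMatrix& X_, const NumericVector& y_, int md, int mn,
          int mt, uint64_t seed)
      : X(X_), y(y_), max_depth(md), min_node(mn), mtry(mt), rng(seed) {}

  int build(std::vector<int>& idx, int depth) {
    int me = (int)nodes.size();
    nodes.emplace_back();
    int n = (int)idx.size();
    double sum = 0.0;
    for (int i : idx) sum += y[i];
    nodes[me].value = sum / n;

    if (depth >= max_depth || n < 2 * min_node) return me;

    int p = X.ncol();
    // feature subset: partial Fisher-Yates over 0..p-1
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j)
      std::swap(feats[j], feats[j + rng.below(p - j)]);

    double best_score = -1.0, base = sum * sum / n;
    int best_f = -1; double best_thr = 0.0;
    std::vector<std::pair<double, double>> xy(n);
    for (int fj = 0; fj < m; ++fj) {
      int f = feats[fj];
      for (int i = 0; i < n; ++i)
        xy[i] = {X(idx[i], f), y[idx[i]]};
      std::sort(xy.begin(), xy.end());
      double s1 = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        s1 += xy[i].second;
        int n1 = i + 1, n2 = n - n1;
        if (xy[i].first == xy[i + 1].first) continue;
        if (n1 < min_node || n2 < min_node) continue;
        double s2 = sum - s1;
        double score = s1 * s1 / n1 + s2 * s2 / n2;
        if (score > best_score) {
          best_score = score;
          best_f = f;
          best_thr = 0.5 * (xy[i].first + xy[i + 1].first);
        }
      }
    }
    if (best_f < 0 || best_score <= base + 1e-12) return me;

    std::vector<int> li, ri;
    li.reserve(n); ri.reserve(n);
    for (int i : idx)
      (X(i, best_f) <= best_thr ? li : ri).push_back(i);
    if ((int)li.size() < min_node || (int)ri.size() < min_node) return me;

    nodes[me].feature = best_f;
    nodes[me].threshold = best_thr;
    int l = build(li, depth + 1);
    int r = build(ri, depth + 1);
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }
};

int descend(const IntegerVector& feature, const NumericVector& threshold,
            const IntegerVector& left, const IntegerVector& right,
            const NumericMatrix& X, int row) {
  int node = 0;
  while (feature[node] >= 0)
    node = (X(row, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
  return node;
}

}  // namespace

// [[Rcpp::export]]
List cpp_tree_fit(NumericMatrix X, NumericVector y, IntegerVector rows,
                  int max_depth, int min_node, int mtry, double seed) {
  std::vector<int> idx(rows.begin(), rows.end());
  Builder b(X, y, max_depth, min_node, mtry, (uint64_t)seed);
  b.nodes.reserve(64);
  b.build(idx, 0);
  int n = (int)b.nodes.size();
  IntegerVector feature(n), left(n), right(n);
  NumericVector threshold(n), value(n);
  for (int i = 0; i < n; ++i) {
    feature[i] = b.nodes[i].feature;
    threshold[i] = b.nodes[i].threshold;
    left[i] = b.nodes[i].left;
    right[i] = b.nodes[i].right;
    value[i] = b.nodes[i].value;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["value"] = value);
}

// [[Rcpp::export]]
NumericVector cpp_tree_predict(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = value[descend(feature, threshold, left, right, X, i)];
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_tree_leaf(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"];
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = descend(feature, threshold, left, right, X, i);
  return out;
}
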