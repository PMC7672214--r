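// CART growing and prediction. Exhaustive Gini split search with the
// deterministic tie-break contract: candidate features scanned in ascending
// index order, candidate thresholds (midpoints between consecutive distinct
// sorted values) in ascending order, and a split is only replaced when its
// weighted child impurity is strictly smaller (beyond a 1e-12 guard), so the
// first-best split wins ties. Feature subsampling for forest trees uses R's
// RNG so a set.seed() in R pins the whole ensemble.

#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

namespace {

struct NodeRec {
  int feature = -1;   // 0-based split feature; -1 => leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  int pred = 0;       // 0-based majority class (first max on ties)
  int n = 0;
  int depth = 0;
  std::vector<double> counts;
};

double gini(const std::vector<int>& cnt, int n) {
  if (n == 0) return 0.0;
  double s = 0.0;
  for (int c : cnt) {
    double p = static_cast<double>(c) / n;
    s += p * p;
  }
  return 1.0 - s;
}

struct Grower {
  const NumericMatrix& X;
  const IntegerVector& y;
  int K;
  int min_split;
  int max_depth;  // -1 => unlimited
  int mtry;       // 0 => all features
  std::vector<NodeRec> nodes;

  Grower(const NumericMatrix& X_, const IntegerVector& y_, int K_,
         int min_split_, int max_depth_, int mtry_)
      : X(X_), y(y_), K(K_), min_split(min_split_), max_depth(max_depth_),
        mtry(mtry_) {}

  std::vector<int> candidate_features() {
    int m = X.ncol();
    if (mtry <= 0 || mtry >= m) {
      std::vector<int> all(m);
      std::iota(all.begin(), all.end(), 0);
      return all;
    }
    std::vector<int> pool(m);
    std::iota(pool.begin(), pool.end(), 0);
    for (int i = 0; i < mtry; ++i) {
      int j = i + static_cast<int>(unif_rand() * (m - i));
      if (j >= m) j = m - 1;
      std::swap(pool[i], pool[j]);
    }
    std::vector<int> chosen(pool.begin(), pool.begin() + mtry);
    std::sort(chosen.begin(), chosen.end());
    return chosen;
  }

  int grow(std::vector<int>& idx, int depth) {
    int id = static_cast<int>(nodes.size());
    nodes.emplace_back();
    int n = static_cast<int>(idx.size());

    std::vector<int> cnt(K, 0);
    for (int i : idx) cnt[y[i]]++;
    int pred = static_cast<int>(
        std::max_element(cnt.begin(), cnt.end()) - cnt.begin());

    NodeRec& self0 = nodes[id];
    self0.n = n;
    self0.depth = depth;
    self0.pred = pred;
    self0.counts.assign(cnt.begin(), cnt.end());

    double parent_gini = gini(cnt, n);
    bool stop = (parent_gini == 0.0) || (n < min_split) ||
                (max_depth >= 0 && depth >= max_depth);
    if (stop) return id;

    // exhaustive best split
    bool found = false;
    int best_f = -1;
    double best_thr = 0.0, best_imp = 1e300;
    std::vector<int> feats = candidate_features();
    std::vector<std::pair<double, int>> vals(n);
    std::vector<int> lcnt(K);
    for (int f : feats) {
      for (int i = 0; i < n; ++i) vals[i] = {X(idx[i], f), y[idx[i]]};
      std::sort(vals.begin(), vals.end(),
                [](const std::pair<double, int>& a,
                   const std::pair<double, int>& b) { return a.first < b.first; });
      if (vals.front().first == vals.back().first) continue;
      std::fill(lcnt.begin(), lcnt.end(), 0);
      int nl = 0;
      for (int i = 0; i < n - 1; ++i) {
        lcnt[vals[i].second]++;
        nl++;
        if (vals[i].first == vals[i + 1].first) continue;
        std::vector<int> rcnt(K);
        for (int c = 0; c < K; ++c) rcnt[c] = cnt[c] - lcnt[c];
        int nr = n - nl;
        double imp = (nl * gini(lcnt, nl) + nr * gini(rcnt, nr)) / n;
        if (imp < best_imp - 1e-12) {
          best_imp = imp;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
          found = true;
        }
      }
    }
    if (!found || best_imp >= parent_gini - 1e-12) return id;  // no useful split

    std::vector<int> lidx, ridx;
    lidx.reserve(n);
    ridx.reserve(n);
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) lidx.push_back(i);
      else ridx.push_back(i);
    }
    int lid = grow(lidx, depth + 1);
    int rid = grow(ridx, depth + 1);
    NodeRec& self = nodes[id];  // re-take: vector may have reallocated
    self.feature = best_f;
    self.threshold = best_thr;
    self.left = lid;
    self.right = rid;
    return id;
  }
};

}  // namespace

// [[Rcpp::export]]
List cart_grow_cpp(NumericMatrix X, IntegerVector y, int K,
                   int min_samples_split, int max_depth, int mtry) {
  int n = X.nrow();
  if (n == 0) stop("empty training set");
  Grower g(X, y, K, min_samples_split, max_depth, mtry);
  std::vector<int> idx(n);
  std::iota(idx.begin(), idx.end(), 0);
  g.grow(idx, 0);

  int p = static_cast<int>(g.nodes.size());
  IntegerVector feature(p), left(p), right(p), pred(p), nn(p), depth(p);
  NumericVector threshold(p);
  NumericMatrix counts(p, K);
  for (int i = 0; i < p; ++i) {
    const NodeRec& nd = g.nodes[i];
    feature[i] = nd.feature;
    threshold[i] = nd.threshold;
    left[i] = nd.left;
    right[i] = nd.right;
    pred[i] = nd.pred;
    nn[i] = nd.n;
    depth[i] = nd.depth;
    for (int c = 0; c < K; ++c) counts(i, c) = nd.counts[c];
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right, _["pred"] = pred,
                      _["n"] = nn, _["depth"] = depth, _["counts"] = counts);
}

// [[Rcpp::export]]
IntegerVector cart_predict_cpp(IntegerVector feature, NumericVector threshold,
                               IntegerVector left, IntegerVector right,
                               IntegerVector pred, NumericMatrix X) {
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
    }
    out[i] = pred[node] + 1;  // 1-based class index for R
  }
  return out;
}
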