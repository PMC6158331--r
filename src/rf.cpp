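// Random Forest core: bagged CART trees with Gini splits and per-node
// random feature subsets. Trees are laid out in preorder so that the left
// child of node i is always i+1; only the right-child index is stored,
// which mirrors the compact on-device node format.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct TreeBuf {
  std::vector<int> feature;     // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> right;       // index of right child (left is idx+1)
  std::vector<int> label;       // leaf label, -1 for internal
};

struct SplitResult {
  int feature = -1;
  double threshold = 0.0;
  double decrease = 0.0;
};

double gini(double n1, double n) {
  if (n <= 0) return 0.0;
  double p1 = n1 / n, p0 = 1.0 - p1;
  return 1.0 - p1 * p1 - p0 * p0;
}

// Best Gini split over `mtry` random features; candidate thresholds are
// midpoints between consecutive distinct sorted values. Ties broken by
// lowest feature index, then lowest threshold (first strict improvement
// wins; features are scanned in ascending index order, thresholds in
// ascending value order).
SplitResult best_split(const NumericMatrix& X, const IntegerVector& y,
                       const std::vector<int>& idx, int mtry,
                       std::mt19937& rng) {
  int p = X.ncol();
  std::vector<int> feats(p);
  for (int f = 0; f < p; ++f) feats[f] = f;
  int m = std::min(mtry, p);
  for (int k = 0; k < m; ++k) {
    int j = k + (int)(rng() % (unsigned)(p - k));
    std::swap(feats[k], feats[j]);
  }
  std::sort(feats.begin(), feats.begin() + m);

  int n = (int)idx.size();
  double n1 = 0;
  for (int i : idx) n1 += y[i];
  double g_parent = gini(n1, n);

  SplitResult best;
  std::vector<std::pair<double, int> > vals(n);
  for (int k = 0; k < m; ++k) {
    int f = feats[k];
    for (int t = 0; t < n; ++t)
      vals[t] = std::make_pair(X(idx[t], f), y[idx[t]]);
    std::sort(vals.begin(), vals.end());
    double left1 = 0;
    for (int t = 0; t < n - 1; ++t) {
      left1 += vals[t].second;
      if (vals[t + 1].first <= vals[t].first) continue;  // not a boundary
      double nl = t + 1, nr = n - nl;
      double dec = g_parent -
        (nl / n) * gini(left1, nl) - (nr / n) * gini(n1 - left1, nr);
      if (dec > best.decrease + 1e-12) {
        best.decrease = dec;
        best.feature = f;
        best.threshold = 0.5 * (vals[t].first + vals[t + 1].first);
      }
    }
  }
  return best;
}

int majority(const IntegerVector& y, const std::vector<int>& idx) {
  double n1 = 0;
  for (int i : idx) n1 += y[i];
  return (n1 * 2 > (double)idx.size()) ? 1 : 0;  // tie -> non-seizure
}

// Preorder recursive growth: emit node, then left subtree, then right.
int grow(const NumericMatrix& X, const IntegerVector& y,
         std::vector<int>& idx, int mtry, int min_node,
         std::mt19937& rng, TreeBuf& tb) {
  int node = (int)tb.feature.size();
  tb.feature.push_back(-1);
  tb.threshold.push_back(0.0);
  tb.right.push_back(-1);
  tb.label.push_back(-1);

  double n1 = 0;
  for (int i : idx) n1 += y[i];
  bool pure = (n1 == 0 || n1 == (double)idx.size());
  if (pure || (int)idx.size() < min_node) {
    tb.label[node] = majority(y, idx);
    return node;
  }
  SplitResult s = best_split(X, y, idx, mtry, rng);
  if (s.feature < 0) {
    tb.label[node] = majority(y, idx);
    return node;
  }
  std::vector<int> left_idx, right_idx;
  for (int i : idx) {
    if (X(i, s.feature) <= s.threshold) left_idx.push_back(i);
    else right_idx.push_back(i);
  }
  if (left_idx.empty() || right_idx.empty()) {
    tb.label[node] = majority(y, idx);
    return node;
  }
  tb.feature[node] = s.feature;
  tb.threshold[node] = s.threshold;
  grow(X, y, left_idx, mtry, min_node, rng, tb);
  tb.right[node] = grow(X, y, right_idx, mtry, min_node, rng, tb);
  return node;
}

int tree_predict_one(const IntegerVector& feature,
                     const NumericVector& threshold,
                     const IntegerVector& right, const IntegerVector& label,
                     const NumericMatrix& X, int row) {
  int node = 0;
  while (feature[node] >= 0) {
    node = (X(row, feature[node]) <= threshold[node]) ? node + 1
                                                      : right[node];
  }
  return label[node];
}

}  // namespace

// [[Rcpp::export(name = ".rf_train_cpp")]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                  int min_node, int seed, bool balanced) {
  int n = X.nrow();
  std::mt19937 rng((unsigned)seed);

  std::vector<int> pos, neg;
  for (int i = 0; i < n; ++i) (y[i] ? pos : neg).push_back(i);
  if (pos.empty() || neg.empty())
    stop("rf_train needs both classes in the training data");

  List trees(n_trees);
  std::vector<int> oob_pos(n, 0), oob_tot(n, 0);

  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> bag(n);
    std::vector<char> inbag(n, 0);
    for (int i = 0; i < n; ++i) {
      int pick;
      if (balanced) {
        const std::vector<int>& cls = (i % 2 == 0) ? pos : neg;
        pick = cls[rng() % cls.size()];
      } else {
        pick = (int)(rng() % (unsigned)n);
      }
      bag[i] = pick;
      inbag[pick] = 1;
    }
    TreeBuf tb;
    grow(X, y, bag, mtry, min_node, rng, tb);
    IntegerVector feature(tb.feature.begin(), tb.feature.end());
    NumericVector threshold(tb.threshold.begin(), tb.threshold.end());
    IntegerVector right(tb.right.begin(), tb.right.end());
    IntegerVector label(tb.label.begin(), tb.label.end());
    trees[t] = List::create(_["feature"] = feature,
                            _["threshold"] = threshold,
                            _["right"] = right, _["label"] = label);
    for (int i = 0; i < n; ++i) {
      if (!inbag[i]) {
        oob_tot[i] += 1;
        oob_pos[i] += tree_predict_one(feature, threshold, right, label, X, i);
      }
    }
  }

  int n_oob = 0, n_err = 0;
  for (int i = 0; i < n; ++i) {
    if (oob_tot[i] > 0) {
      ++n_oob;
      int pred = (2 * oob_pos[i] > oob_tot[i]) ? 1 : 0;
      if (pred != y[i]) ++n_err;
    }
  }
  double oob_error = n_oob ? (double)n_err / n_oob : NA_REAL;
  return List::create(_["trees"] = trees, _["oob_error"] = oob_error);
}

// [[Rcpp::export(name = ".rf_votes_cpp")]]
NumericVector rf_votes_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), nt = trees.size();
  NumericVector out(n);
  for (int t = 0; t < nt; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector right = tr["right"];
    IntegerVector label = tr["label"];
    for (int i = 0; i < n; ++i)
      out[i] += tree_predict_one(feature, threshold, right, label, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= nt;
  return out;
}
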