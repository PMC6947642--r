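// Gradient-boosted regression trees with least-absolute-deviation loss.
//
// Boosting follows the classical LAD recipe: F0 = median(y); at every stage a
// depth-limited CART regression tree is grown (squared-error splits) on the
// pseudo-residuals sign(y - F), each terminal leaf is then re-valued with the
// median of the raw residuals of its in-bag samples (the LAD line search), and
// F is updated by learning_rate * leaf value.  Row subsampling draws
// floor(subsample * n) in-bag rows per stage without replacement using R's RNG,
// so a set.seed() on the R side makes fits bit-reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Tree {
  // flat arrays; leaf nodes have feature == -1
  std::vector<int> feature;
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> value;
};

double median_of(std::vector<double> v) {
  const size_t n = v.size();
  if (n == 0) return 0.0;
  std::sort(v.begin(), v.end());
  if (n % 2 == 1) return v[n / 2];
  return 0.5 * (v[n / 2 - 1] + v[n / 2]);
}

// Grow one node over `idx` (row indices into X), targets r (pseudo-residuals).
// Returns node id.
int grow(Tree& tree, const NumericMatrix& X, const std::vector<double>& r,
         std::vector<int>& idx, int lo, int hi, int depth, int max_depth,
         int min_samples_split) {
  const int n = hi - lo;
  const int node = static_cast<int>(tree.feature.size());
  tree.feature.push_back(-1);
  tree.threshold.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  tree.value.push_back(0.0);

  double sum = 0.0;
  for (int k = lo; k < hi; ++k) sum += r[idx[k]];
  tree.value[node] = sum / n;  // placeholder, leaves re-valued by line search

  if (depth >= max_depth || n < min_samples_split || n < 2) return node;

  // exhaustive best squared-error split
  const int p = X.ncol();
  double best_gain = 1e-12;  // require strictly positive gain
  int best_f = -1;
  double best_thr = 0.0;

  std::vector<std::pair<double, double> > xv(n);  // (x, r)
  for (int j = 0; j < p; ++j) {
    for (int k = 0; k < n; ++k) {
      const int i = idx[lo + k];
      xv[k] = std::make_pair(X(i, j), r[i]);
    }
    std::sort(xv.begin(), xv.end());
    if (xv.front().first == xv.back().first) continue;  // constant feature
    double lsum = 0.0;
    for (int k = 0; k < n - 1; ++k) {
      lsum += xv[k].second;
      if (xv[k].first == xv[k + 1].first) continue;  // no split inside ties
      const int nl = k + 1, nr = n - nl;
      const double rsum = sum - lsum;
      // SSE reduction = nl*mul^2 + nr*mur^2 - n*mu^2 (constant dropped)
      const double gain = lsum * lsum / nl + rsum * rsum / nr - sum * sum / n;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = j;
        best_thr = 0.5 * (xv[k].first + xv[k + 1].first);
      }
    }
  }
  if (best_f < 0) return node;

  // partition idx[lo:hi) in place
  int mid = lo;
  for (int k = lo; k < hi; ++k) {
    if (X(idx[k], best_f) <= best_thr) std::swap(idx[k], idx[mid++]);
  }
  if (mid == lo || mid == hi) return node;  // degenerate, keep as leaf

  tree.feature[node] = best_f;
  tree.threshold[node] = best_thr;
  tree.left[node] = grow(tree, X, r, idx, lo, mid, depth + 1, max_depth,
                         min_samples_split);
  tree.right[node] = grow(tree, X, r, idx, mid, hi, depth + 1, max_depth,
                          min_samples_split);
  return node;
}

int leaf_of(const Tree& tree, const NumericMatrix& X, int i) {
  int node = 0;
  while (tree.feature[node] >= 0) {
    node = (X(i, tree.feature[node]) <= tree.threshold[node]) ? tree.left[node]
                                                              : tree.right[node];
  }
  return node;
}

}  // namespace

// [[Rcpp::export(name = ".gbr_fit_cpp")]]
List gbr_fit_cpp(NumericMatrix X, NumericVector y, int n_estimators,
                 double learning_rate, int max_depth, int min_samples_split,
                 double subsample) {
  const int n = X.nrow();
  if (n == 0 || y.size() != n) stop("X and y sizes disagree");

  std::vector<double> yv(y.begin(), y.end());
  const double f0 = median_of(yv);
  std::vector<double> F(n, f0);

  const int n_bag = std::max(1, static_cast<int>(std::floor(subsample * n)));
  std::vector<int> perm(n);

  List trees(n_estimators);
  for (int m = 0; m < n_estimators; ++m) {
    // in-bag rows: first n_bag of a Fisher-Yates shuffle driven by R's RNG
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = 0; i < n_bag; ++i) {
      const int j = i + static_cast<int>(unif_rand() * (n - i));
      std::swap(perm[i], perm[std::min(j, n - 1)]);
    }
    std::vector<int> bag(perm.begin(), perm.begin() + n_bag);

    // LAD pseudo-residuals
    std::vector<double> r(n, 0.0);
    for (int i = 0; i < n; ++i) {
      const double d = yv[i] - F[i];
      r[i] = (d > 0) - (d < 0);
    }

    Tree tree;
    std::vector<int> idx(bag);
    grow(tree, X, r, idx, 0, static_cast<int>(idx.size()), 0, max_depth,
         min_samples_split);

    // line search: leaf value <- median(y - F) over in-bag rows in the leaf
    std::map<int, std::vector<double> > leaf_res;
    for (size_t k = 0; k < bag.size(); ++k) {
      const int i = bag[k];
      leaf_res[leaf_of(tree, X, i)].push_back(yv[i] - F[i]);
    }
    for (std::map<int, std::vector<double> >::iterator it = leaf_res.begin();
         it != leaf_res.end(); ++it) {
      tree.value[it->first] = median_of(it->second);
    }
    // leaves never reached by in-bag rows keep their mean-gradient placeholder,
    // which cannot happen for leaves grown from the bag itself.

    // update F on all rows
    for (int i = 0; i < n; ++i) {
      F[i] += learning_rate * tree.value[leaf_of(tree, X, i)];
    }

    trees[m] = List::create(_["feature"] = wrap(tree.feature),
                            _["threshold"] = wrap(tree.threshold),
                            _["left"] = wrap(tree.left),
                            _["right"] = wrap(tree.right),
                            _["value"] = wrap(tree.value));
  }

  return List::create(_["f0"] = f0, _["trees"] = trees,
                      _["learning_rate"] = learning_rate,
                      _["train_pred"] = wrap(F));
}

// [[Rcpp::export(name = ".gbr_predict_cpp")]]
NumericVector gbr_predict_cpp(List model, NumericMatrix X) {
  const int n = X.nrow();
  const double f0 = as<double>(model["f0"]);
  const double lr = as<double>(model["learning_rate"]);
  List trees = model["trees"];
  NumericVector out(n, f0);

  for (int m = 0; m < trees.size(); ++m) {
    List tl = trees[m];
    IntegerVector feature = tl["feature"];
    NumericVector threshold = tl["threshold"];
    IntegerVector left = tl["left"], right = tl["right"];
    NumericVector value = tl["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0) {
        node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
      }
      out[i] += lr * value[node];
    }
  }
  return out;
}
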