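// Regression random forest recording per-split impurity reductions,
// the primitive behind gradient-style cumulative importance curves.
// Variance-reduction (SSE) splitting, bootstrap rows, random predictor
// subset per split, out-of-bag predictions.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

struct Node {
  int var = -1;          // -1 -> leaf
  double thr = 0.0;
  int left = -1, right = -1;
  double value = 0.0;
};

struct SplitRec {
  int var;
  double thr;
  double gain;
};

static void grow(const NumericMatrix& X, const NumericVector& y,
                 std::vector<int>& rows, int lo, int hi,
                 int mtry, int min_leaf, std::mt19937& rng,
                 std::vector<Node>& nodes, int node_id,
                 std::vector<SplitRec>& splits) {
  const int n = hi - lo;
  double s = 0.0, s2 = 0.0;
  for (int i = lo; i < hi; ++i) {
    s += y[rows[i]];
    s2 += y[rows[i]] * y[rows[i]];
  }
  nodes[node_id].value = s / n;
  const double sse_parent = s2 - s * s / n;
  if (n < 2 * min_leaf || sse_parent <= 1e-12) return;

  const int p = X.ncol();
  std::vector<int> vars(p);
  for (int j = 0; j < p; ++j) vars[j] = j;
  // partial Fisher-Yates for the mtry candidate predictors
  for (int j = 0; j < mtry && j < p; ++j) {
    std::uniform_int_distribution<int> U(j, p - 1);
    std::swap(vars[j], vars[U(rng)]);
  }

  double best_gain = 0.0, best_thr = 0.0;
  int best_var = -1;
  std::vector<std::pair<double, double>> xy(n);
  for (int jj = 0; jj < mtry && jj < p; ++jj) {
    const int v = vars[jj];
    for (int i = 0; i < n; ++i) {
      xy[i] = {X(rows[lo + i], v), y[rows[lo + i]]};
    }
    std::sort(xy.begin(), xy.end());
    double sl = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      sl += xy[i].second;
      const int nl = i + 1, nr = n - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      if (xy[i].first == xy[i + 1].first) continue;
      const double sr = s - sl;
      const double gain = sl * sl / nl + sr * sr / nr - s * s / n;
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_var = v;
        best_thr = 0.5 * (xy[i].first + xy[i + 1].first);
      }
    }
  }
  if (best_var < 0) return;

  // partition rows[lo, hi) by the chosen split
  int mid = lo;
  for (int i = lo; i < hi; ++i) {
    if (X(rows[i], best_var) <= best_thr) std::swap(rows[mid++], rows[i]);
  }
  if (mid == lo || mid == hi) return;  // numerical guard

  nodes[node_id].var = best_var;
  nodes[node_id].thr = best_thr;
  splits.push_back({best_var, best_thr, best_gain});

  nodes.push_back(Node());
  const int left_id = (int)nodes.size() - 1;
  nodes.push_back(Node());
  const int right_id = (int)nodes.size() - 1;
  nodes[node_id].left = left_id;
  nodes[node_id].right = right_id;
  grow(X, y, rows, lo, mid, mtry, min_leaf, rng, nodes, left_id, splits);
  grow(X, y, rows, mid, hi, mtry, min_leaf, rng, nodes, right_id, splits);
}

static double predict_one(const std::vector<Node>& nodes,
                          const NumericMatrix& X, int row,
                          int override_var = -1, double override_val = 0.0) {
  int id = 0;
  while (nodes[id].var >= 0) {
    const double xv = (nodes[id].var == override_var)
                          ? override_val : X(row, nodes[id].var);
    id = (xv <= nodes[id].thr) ? nodes[id].left : nodes[id].right;
  }
  return nodes[id].value;
}

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                int min_leaf, int seed) {
  const int n = X.nrow();
  const int p = X.ncol();
  std::vector<SplitRec> all_splits;
  NumericVector oob_sum(n, 0.0);
  IntegerVector oob_n(n, 0);
  // per-predictor OOB permutation importance (mean MSE increase)
  std::vector<double> perm_imp(p, 0.0);
  std::vector<int> perm_trees(p, 0);

  for (int t = 0; t < n_trees; ++t) {
    std::mt19937 rng((unsigned)(seed) * 2654435761u + (unsigned)t);
    std::uniform_int_distribution<int> U(0, n - 1);
    std::vector<int> inbag(n, 0);
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) {
      rows[i] = U(rng);
      inbag[rows[i]]++;
    }
    std::vector<Node> nodes(1);
    std::vector<SplitRec> splits;
    grow(X, y, rows, 0, n, mtry, min_leaf, rng, nodes, 0, splits);
    for (const auto& sp : splits) all_splits.push_back(sp);

    std::vector<int> oob;
    for (int i = 0; i < n; ++i) {
      if (inbag[i] == 0) {
        oob_sum[i] += predict_one(nodes, X, i);
        oob_n[i]++;
        oob.push_back(i);
      }
    }
    if (oob.size() < 2 || splits.empty()) continue;

    std::vector<bool> used(p, false);
    for (const auto& sp : splits) used[sp.var] = true;
    double mse_base = 0.0;
    for (int i : oob) {
      const double e = y[i] - predict_one(nodes, X, i);
      mse_base += e * e;
    }
    mse_base /= oob.size();
    std::vector<int> perm(oob);
    for (int v = 0; v < p; ++v) {
      if (!used[v]) { perm_trees[v]++; continue; }  // zero increase
      std::shuffle(perm.begin(), perm.end(), rng);
      double mse_perm = 0.0;
      for (size_t i = 0; i < oob.size(); ++i) {
        const double e =
            y[oob[i]] - predict_one(nodes, X, oob[i], v, X(perm[i], v));
        mse_perm += e * e;
      }
      mse_perm /= oob.size();
      perm_imp[v] += mse_perm - mse_base;
      perm_trees[v]++;
    }
  }

  const int m = (int)all_splits.size();
  IntegerVector sv(m);
  NumericVector st(m), sg(m);
  for (int i = 0; i < m; ++i) {
    sv[i] = all_splits[i].var + 1;  // 1-based for R
    st[i] = all_splits[i].thr;
    sg[i] = all_splits[i].gain;
  }
  NumericVector pi(p);
  for (int v = 0; v < p; ++v) {
    pi[v] = perm_trees[v] > 0 ? perm_imp[v] / perm_trees[v] : 0.0;
  }
  return List::create(_["var"] = sv, _["threshold"] = st, _["gain"] = sg,
                      _["oob_sum"] = oob_sum, _["oob_n"] = oob_n,
                      _["perm_importance"] = pi);
}
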