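// Regression random forest: bagged CART with mtry feature subsampling,
// out-of-bag error and OOB permutation importance. Uses R's RNG so results
// are a pure function of the R-side seed.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> var;       // split variable, -1 for leaf
  std::vector<double> split;  // split value (go left if x <= split)
  std::vector<int> left, right;
  std::vector<double> pred;   // node mean (used at leaves)
};

inline int randi(int n) {
  int v = static_cast<int>(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

// partial Fisher-Yates: first `take` entries of 0..p-1 in random order
void sample_vars(std::vector<int>& pool, int take) {
  const int p = static_cast<int>(pool.size());
  for (int i = 0; i < take; ++i) {
    int j = i + randi(p - i);
    std::swap(pool[i], pool[j]);
  }
}

int build_node(Tree& tree, const NumericMatrix& X, const NumericVector& y,
               std::vector<int>& idx, int lo, int hi, int mtry, int nodesize,
               std::vector<int>& varpool,
               std::vector<std::pair<double, double> >& buf) {
  const int m = hi - lo;
  double sum = 0.0, ss = 0.0;
  for (int t = lo; t < hi; ++t) { sum += y[idx[t]]; ss += y[idx[t]] * y[idx[t]]; }
  const double mean = sum / m;
  const double sse = ss - sum * sum / m;

  const int node = static_cast<int>(tree.var.size());
  tree.var.push_back(-1); tree.split.push_back(0.0);
  tree.left.push_back(-1); tree.right.push_back(-1);
  tree.pred.push_back(mean);

  if (m <= nodesize || sse <= 1e-12) return node;

  sample_vars(varpool, mtry);
  int best_var = -1;
  double best_score = sum * sum / m;  // score of no split
  double best_cut = 0.0;
  for (int v = 0; v < mtry; ++v) {
    const int j = varpool[v];
    buf.resize(m);
    for (int t = 0; t < m; ++t)
      buf[t] = std::make_pair(X(idx[lo + t], j), y[idx[lo + t]]);
    std::sort(buf.begin(), buf.end());
    double sl = 0.0;
    for (int k = 1; k < m; ++k) {
      sl += buf[k - 1].second;
      if (buf[k - 1].first >= buf[k].first) continue;  // tied x, no cut here
      const double sr = sum - sl;
      const double score = sl * sl / k + sr * sr / (m - k);
      if (score > best_score + 1e-12) {
        best_score = score;
        best_var = j;
        best_cut = 0.5 * (buf[k - 1].first + buf[k].first);
      }
    }
  }
  if (best_var < 0) return node;  // selected predictors all constant here

  int mid = lo;
  for (int t = lo; t < hi; ++t)
    if (X(idx[t], best_var) <= best_cut) std::swap(idx[t], idx[mid++]);
  if (mid == lo || mid == hi) return node;  // numerical guard

  tree.var[node] = best_var;
  tree.split[node] = best_cut;
  tree.left[node] = build_node(tree, X, y, idx, lo, mid, mtry, nodesize,
                               varpool, buf);
  tree.right[node] = build_node(tree, X, y, idx, mid, hi, mtry, nodesize,
                                varpool, buf);
  return node;
}

double predict_row(const Tree& tree, const NumericMatrix& X, int row,
                   int perm_var = -1, double perm_val = 0.0) {
  int node = 0;
  while (tree.var[node] >= 0) {
    const int j = tree.var[node];
    const double x = (j == perm_var) ? perm_val : X(row, j);
    node = (x <= tree.split[node]) ? tree.left[node] : tree.right[node];
  }
  return tree.pred[node];
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int ntree, int mtry,
                int nodesize, bool importance) {
  const int n = X.nrow(), p = X.ncol();
  if (mtry < 1 || mtry > p) stop("mtry out of range");
  if (ntree < 1) stop("ntree must be >= 1");

  std::vector<double> oob_sum(n, 0.0);
  std::vector<int> oob_cnt(n, 0);
  std::vector<double> imp(p, 0.0);
  std::vector<int> inbag(n);
  std::vector<int> idx; idx.reserve(n);
  std::vector<int> oob; oob.reserve(n);
  std::vector<int> varpool(p);
  std::vector<std::pair<double, double> > buf;
  std::vector<double> permx; permx.reserve(n);

  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    idx.clear();
    for (int i = 0; i < n; ++i) {
      const int r = randi(n);
      ++inbag[r];
      idx.push_back(r);
    }
    for (int j = 0; j < p; ++j) varpool[j] = j;
    Tree tree;
    build_node(tree, X, y, idx, 0, n, mtry, nodesize, varpool, buf);

    oob.clear();
    for (int i = 0; i < n; ++i) if (inbag[i] == 0) oob.push_back(i);
    if (oob.empty()) continue;

    double mse0 = 0.0;
    for (size_t q = 0; q < oob.size(); ++q) {
      const double pr = predict_row(tree, X, oob[q]);
      oob_sum[oob[q]] += pr;
      ++oob_cnt[oob[q]];
      const double e = y[oob[q]] - pr;
      mse0 += e * e;
    }
    mse0 /= oob.size();

    if (importance) {
      for (int j = 0; j < p; ++j) {
        permx.clear();
        for (size_t q = 0; q < oob.size(); ++q) permx.push_back(X(oob[q], j));
        for (int q = static_cast<int>(permx.size()) - 1; q > 0; --q)
          std::swap(permx[q], permx[randi(q + 1)]);
        double msej = 0.0;
        for (size_t q = 0; q < oob.size(); ++q) {
          const double e =
              y[oob[q]] - predict_row(tree, X, oob[q], j, permx[q]);
          msej += e * e;
        }
        msej /= oob.size();
        imp[j] += msej - mse0;
      }
    }
  }

  NumericVector oob_pred(n, NA_REAL);
  double mse = 0.0;
  int used = 0;
  for (int i = 0; i < n; ++i) {
    if (oob_cnt[i] > 0) {
      oob_pred[i] = oob_sum[i] / oob_cnt[i];
      const double e = y[i] - oob_pred[i];
      mse += e * e;
      ++used;
    }
  }
  if (used == 0) stop("no out-of-bag predictions; increase ntree");
  mse /= used;

  NumericVector imp_out(p);
  for (int j = 0; j < p; ++j) imp_out[j] = imp[j] / ntree;

  return List::create(_["oob_pred"] = oob_pred, _["oob_mse"] = mse,
                      _["importance"] = imp_out, _["n_oob"] = used);
}
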