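#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <numeric>

using namespace Rcpp;

// Weighted regression tree with per-node random feature subsets.
//
// Split quality: decrease in raw-weight SSE,
//   gain = SSE(v) - SSE(v_l) - SSE(v_r),  SSE(v) = sum_{n in v} w*_n (y_n - ybar_w(v))^2,
// which equals the node-normalized error improvement
//   w_an(v) * (MSE(v) - w_ch(v_r) MSE(v_r) - w_ch(v_l) MSE(v_l))
// up to the positive node-constant factor 1 / sum_{root} w*, with
// w_an, w_ch the weight-mass fractions and MSE the weighted mean squared
// error under per-node normalized sample weights. Argmax is therefore
// identical; importances are accumulated on the normalized scale.
//
// Candidate splits are midpoints between consecutive distinct sorted values.
// Ties in gain are broken by (lower feature index, lower split value):
// features are scanned in ascending index order, split values in ascending
// order, and only strictly larger gains replace the incumbent.

namespace {

struct Tree {
  std::vector<int> feature;      // 1-based split feature, 0 = leaf
  std::vector<double> split;     // split point; x < split goes left
  std::vector<int> left, right;  // 1-based child node ids, 0 = none
  std::vector<double> value;     // w*-weighted mean of y_value over members
  std::vector<double> uvalue;    // unweighted mean of y_value over members
  std::vector<int> cls;          // leaf class label: mode of raw member counts, tie -> 0
  std::vector<double> w0, w1;    // raw w* mass of members by class
  std::vector<int> n0, n1;       // raw member counts (bootstrap multiplicity) by class
};

struct Builder {
  const NumericMatrix& X;
  const NumericVector& ys;   // response used for splitting
  const NumericVector& yv;   // response stored as leaf value
  const NumericVector& w;    // raw sample weights w*
  const IntegerVector& cl;   // 0/1 class of each row
  int mtry, min_leaf, P;
  double w_root;
  Tree tree;
  std::vector<double> importance;  // per-feature, Eq.-(4)-scaled gains

  Builder(const NumericMatrix& X_, const NumericVector& ys_,
          const NumericVector& yv_, const NumericVector& w_,
          const IntegerVector& cl_, int mtry_, int min_leaf_)
      : X(X_), ys(ys_), yv(yv_), w(w_), cl(cl_), mtry(mtry_),
        min_leaf(min_leaf_), P(X_.ncol()), w_root(0.0),
        importance(X_.ncol(), 0.0) {}

  // partial Fisher-Yates draw of mtry feature indices (0-based), returned sorted
  std::vector<int> draw_features() {
    std::vector<int> pool(P);
    std::iota(pool.begin(), pool.end(), 0);
    int m = std::min(mtry, P);
    for (int i = 0; i < m; ++i) {
      int j = i + (int)std::floor(unif_rand() * (P - i));
      if (j >= P) j = P - 1;
      std::swap(pool[i], pool[j]);
    }
    std::vector<int> out(pool.begin(), pool.begin() + m);
    std::sort(out.begin(), out.end());
    return out;
  }

  int new_node(const std::vector<int>& members) {
    double sw = 0.0, swv = 0.0, sv = 0.0, m0 = 0.0, m1 = 0.0;
    int c0 = 0, c1 = 0;
    for (int i : members) {
      sw += w[i];
      swv += w[i] * yv[i];
      sv += yv[i];
      if (cl[i] == 1) { m1 += w[i]; ++c1; } else { m0 += w[i]; ++c0; }
    }
    tree.feature.push_back(0);
    tree.split.push_back(NA_REAL);
    tree.left.push_back(0);
    tree.right.push_back(0);
    tree.value.push_back(swv / sw);
    tree.uvalue.push_back(sv / (double)members.size());
    // leaf label: majority by w* mass (ties resistant). With uniform weights
    // this is the plain count mode; with imbalance weights it mirrors what
    // duplicating minority rows would do to the count mode, keeping the
    // weight and upsampling countermeasures equivalent in the class channel.
    tree.cls.push_back(m1 > m0 ? 1 : 0);
    tree.w0.push_back(m0);
    tree.w1.push_back(m1);
    tree.n0.push_back(c0);
    tree.n1.push_back(c1);
    return (int)tree.feature.size() - 1;
  }

  void build(std::vector<int>& members, int node_id) {
    int n = (int)members.size();
    double sw = 0.0, swy = 0.0, swyy = 0.0;
    for (int i : members) {
      sw += w[i];
      swy += w[i] * ys[i];
      swyy += w[i] * ys[i] * ys[i];
    }
    double sse_parent = swyy - swy * swy / sw;
    if (n < 2 * min_leaf || sse_parent <= 1e-12) return;  // leaf

    std::vector<int> feats = draw_features();
    int best_f = -1, best_pos = -1;
    double best_split = 0.0, best_gain = 0.0;
    // candidates whose gains agree to within ~1e-9 of the node error are
    // ties (e.g. two features inducing the same partition); the first in
    // (feature, split) order wins
    const double tie_tol = 1e-9 * sse_parent;
    std::vector<int> ord(members);

    for (int f : feats) {
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        double xa = X(a, f), xb = X(b, f);
        if (xa != xb) return xa < xb;
        return a < b;
      });
      double cw = 0.0, cwy = 0.0, cwyy = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        int r = ord[i];
        cw += w[r];
        cwy += w[r] * ys[r];
        cwyy += w[r] * ys[r] * ys[r];
        double xl = X(r, f), xr = X(ord[i + 1], f);
        if (xl >= xr) continue;  // not a boundary between distinct values
        int n_left = i + 1;
        if (n_left < min_leaf || n - n_left < min_leaf) continue;
        double sse_l = cwyy - cwy * cwy / cw;
        double rw = sw - cw, rwy = swy - cwy, rwyy = swyy - cwyy;
        double sse_r = rwyy - rwy * rwy / rw;
        double gain = sse_parent - sse_l - sse_r;
        if (gain > best_gain + tie_tol) {
          best_gain = gain;
          best_f = f;
          best_split = 0.5 * (xl + xr);
          best_pos = n_left;
        }
      }
    }
    if (best_f < 0) return;  // no admissible split among drawn features

    importance[best_f] += best_gain / w_root;

    std::vector<int> lm, rm;
    lm.reserve(best_pos);
    rm.reserve(n - best_pos);
    for (int i : members) {
      if (X(i, best_f) < best_split) lm.push_back(i); else rm.push_back(i);
    }
    members.clear();
    members.shrink_to_fit();

    tree.feature[node_id] = best_f + 1;
    tree.split[node_id] = best_split;
    int lid = new_node(lm);
    tree.left[node_id] = lid + 1;
    build(lm, lid);
    int rid = new_node(rm);
    tree.right[node_id] = rid + 1;
    build(rm, rid);
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_build_tree(NumericMatrix X, NumericVector y_split, NumericVector y_value,
                    NumericVector w, IntegerVector cls, IntegerVector boot,
                    int mtry, int min_leaf) {
  Builder b(X, y_split, y_value, w, cls, mtry, min_leaf);
  std::vector<int> members;
  members.reserve(boot.size());
  for (int i = 0; i < boot.size(); ++i) members.push_back(boot[i] - 1);
  for (int i : members) b.w_root += w[i];
  int root = b.new_node(members);
  b.build(members, root);
  return List::create(
      _["feature"] = wrap(b.tree.feature), _["split"] = wrap(b.tree.split),
      _["left"] = wrap(b.tree.left), _["right"] = wrap(b.tree.right),
      _["value"] = wrap(b.tree.value), _["uvalue"] = wrap(b.tree.uvalue),
      _["class"] = wrap(b.tree.cls),
      _["w0"] = wrap(b.tree.w0), _["w1"] = wrap(b.tree.w1),
      _["n0"] = wrap(b.tree.n0), _["n1"] = wrap(b.tree.n1),
      _["importance"] = wrap(b.importance));
}

static int traverse_one(const IntegerVector& feature, const NumericVector& split,
                        const IntegerVector& left, const IntegerVector& right,
                        const NumericMatrix& X, int row) {
  int node = 0;
  while (feature[node] > 0) {
    node = (X(row, feature[node] - 1) < split[node] ? left[node] : right[node]) - 1;
  }
  return node;
}

// Drop every row of newX down every tree; per (tree, query) return the
// reached leaf's stored value, class label, per-class raw weight mass and
// the 1-based leaf node id.
// [[Rcpp::export]]
List cpp_forest_traverse(List trees, NumericMatrix newX) {
  int B = trees.size(), n = newX.nrow();
  NumericMatrix value(B, n), uvalue(B, n), w0(B, n), w1(B, n);
  IntegerMatrix cls(B, n), leaf(B, n);
  for (int b = 0; b < B; ++b) {
    List tr = trees[b];
    IntegerVector feature = tr["feature"], left = tr["left"], right = tr["right"];
    IntegerVector tcls = tr["class"];
    NumericVector split = tr["split"], val = tr["value"], uval = tr["uvalue"];
    NumericVector tw0 = tr["w0"], tw1 = tr["w1"];
    for (int q = 0; q < n; ++q) {
      int node = traverse_one(feature, split, left, right, newX, q);
      value(b, q) = val[node];
      uvalue(b, q) = uval[node];
      cls(b, q) = tcls[node];
      w0(b, q) = tw0[node];
      w1(b, q) = tw1[node];
      leaf(b, q) = node + 1;
    }
  }
  return List::create(_["value"] = value, _["uvalue"] = uvalue, _["class"] = cls,
                      _["w0"] = w0, _["w1"] = w1, _["leaf"] = leaf);
}
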