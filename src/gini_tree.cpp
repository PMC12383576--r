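#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Best-first CART grower for binary classification with a Gini criterion.
// Used for (a) single-feature discretization trees constrained by a depth
// and leaf-node budget and (b) the trees of the meta-forest (bootstrap rows
// supplied by the caller, per-split random feature subsetting via R's RNG).
//
// Conventions (fixed, relied on by tests):
//  - split sends x <= threshold to the left child (intervals right-closed);
//  - candidate thresholds are midpoints of consecutive distinct values;
//  - ties in impurity decrease (within TOL) break to the smaller threshold
//    within a feature and to the lower feature index across features;
//  - best-first growth: the pending node with the largest impurity decrease
//    is realized first (ties to the earlier-created node).

static const double TOL = 1e-9;

struct OpenNode {
  int id;
  int depth;
  std::vector<int> rows;   // 0-based row indices into X
  int n_pos;
  bool has_split;
  int best_feat;           // 0-based
  double best_thr;
  double best_dec;         // unnormalized impurity decrease (count scale)
};

struct NodeRec {
  int feature = -1;        // 0-based, -1 = leaf
  double threshold = NA_REAL;
  int left = -1, right = -1;
  int depth = 0;
  int n = 0, n_pos = 0;
};

// unnormalized gini: n * (1 - p0^2 - p1^2) = n - (pos^2 + neg^2)/n
static inline double gini_term(double n, double pos) {
  if (n <= 0) return 0.0;
  double neg = n - pos;
  return n - (pos * pos + neg * neg) / n;
}

// Sample mtry distinct feature indices from 0..p-1 using R's RNG
// (partial Fisher-Yates), then sort ascending for deterministic tie-breaks.
static std::vector<int> sample_features(int p, int mtry) {
  std::vector<int> feats(p);
  for (int i = 0; i < p; ++i) feats[i] = i;
  if (mtry >= p) return feats;
  for (int i = 0; i < mtry; ++i) {
    int j = i + (int)std::floor(unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(feats[i], feats[j]);
  }
  feats.resize(mtry);
  std::sort(feats.begin(), feats.end());
  return feats;
}

// Find the best split of `nd` over a feature subset; fills best_* fields.
static void find_best_split(OpenNode &nd, const NumericMatrix &X,
                            const IntegerVector &y, int mtry, int min_leaf) {
  nd.has_split = false;
  const int n = (int)nd.rows.size();
  if (n < 2 * min_leaf) return;
  const int p = X.ncol();
  std::vector<int> feats = sample_features(p, mtry);

  double parent = gini_term((double)n, (double)nd.n_pos);
  std::vector<std::pair<double, int>> vals(n); // (x, y)

  for (size_t fi = 0; fi < feats.size(); ++fi) {
    int f = feats[fi];
    for (int i = 0; i < n; ++i) {
      int r = nd.rows[i];
      vals[i] = std::make_pair(X(r, f), y[r]);
    }
    std::sort(vals.begin(), vals.end());
    double pos_l = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      pos_l += vals[i].second;
      if (vals[i].first == vals[i + 1].first) continue; // not a boundary
      int n_l = i + 1, n_r = n - n_l;
      if (n_l < min_leaf || n_r < min_leaf) continue;
      double dec = parent - gini_term((double)n_l, pos_l)
                          - gini_term((double)n_r, (double)nd.n_pos - pos_l);
      double thr = vals[i].first + 0.5 * (vals[i + 1].first - vals[i].first);
      if (!nd.has_split || dec > nd.best_dec + TOL) {
        nd.has_split = true;
        nd.best_dec = dec;
        nd.best_feat = f;
        nd.best_thr = thr;
      }
      // ties: ascending feature order and ascending threshold scan mean the
      // incumbent already has the smaller (feature, threshold); keep it.
    }
  }
}

// [[Rcpp::export(name = ".grow_gini_tree")]]
List grow_gini_tree(NumericMatrix X, IntegerVector y, IntegerVector rows,
                    int max_depth, int max_leaves, int min_leaf,
                    int min_split, int mtry) {
  const int nr = rows.size();
  if (nr < 1) stop("empty row set");
  std::vector<NodeRec> nodes;
  std::vector<OpenNode> open;

  OpenNode root;
  root.id = 0;
  root.depth = 0;
  root.rows.resize(nr);
  root.n_pos = 0;
  for (int i = 0; i < nr; ++i) {
    root.rows[i] = rows[i] - 1;
    root.n_pos += y[root.rows[i]];
  }
  NodeRec rec;
  rec.n = nr;
  rec.n_pos = root.n_pos;
  rec.depth = 0;
  nodes.push_back(rec);

  bool splittable = root.depth < max_depth && nr >= min_split &&
                    root.n_pos > 0 && root.n_pos < nr;
  if (splittable) find_best_split(root, X, y, mtry, min_leaf);
  if (root.has_split) open.push_back(root);

  int n_leaves = 1;
  while (n_leaves < max_leaves && !open.empty()) {
    // pick open node with largest decrease; ties -> earliest id
    size_t best = 0;
    for (size_t i = 1; i < open.size(); ++i) {
      if (open[i].best_dec > open[best].best_dec + TOL) best = i;
      else if (open[i].best_dec >= open[best].best_dec - TOL &&
               open[i].id < open[best].id) best = i;
    }
    OpenNode nd = open[best];
    open.erase(open.begin() + best);

    // realize the split
    OpenNode lft, rgt;
    lft.depth = rgt.depth = nd.depth + 1;
    lft.n_pos = rgt.n_pos = 0;
    for (size_t i = 0; i < nd.rows.size(); ++i) {
      int r = nd.rows[i];
      if (X(r, nd.best_feat) <= nd.best_thr) {
        lft.rows.push_back(r);
        lft.n_pos += y[r];
      } else {
        rgt.rows.push_back(r);
        rgt.n_pos += y[r];
      }
    }
    lft.id = (int)nodes.size();
    rgt.id = (int)nodes.size() + 1;
    nodes[nd.id].feature = nd.best_feat;
    nodes[nd.id].threshold = nd.best_thr;
    nodes[nd.id].left = lft.id;
    nodes[nd.id].right = rgt.id;

    OpenNode *kids[2] = { &lft, &rgt };
    for (int c = 0; c < 2; ++c) {
      OpenNode &k = *kids[c];
      NodeRec kr;
      kr.n = (int)k.rows.size();
      kr.n_pos = k.n_pos;
      kr.depth = k.depth;
      nodes.push_back(kr);
      bool ok = k.depth < max_depth && kr.n >= min_split &&
                k.n_pos > 0 && k.n_pos < kr.n;
      if (ok) {
        find_best_split(k, X, y, mtry, min_leaf);
        if (k.has_split) open.push_back(k);
      }
    }
    ++n_leaves;
  }

  const int nn = (int)nodes.size();
  IntegerVector feature(nn), left(nn), right(nn), nvec(nn), npos(nn), depth(nn);
  NumericVector threshold(nn), q1(nn);
  for (int i = 0; i < nn; ++i) {
    const NodeRec &r = nodes[i];
    feature[i] = r.feature >= 0 ? r.feature + 1 : NA_INTEGER;
    threshold[i] = r.threshold;
    left[i] = r.left >= 0 ? r.left + 1 : NA_INTEGER;
    right[i] = r.right >= 0 ? r.right + 1 : NA_INTEGER;
    nvec[i] = r.n;
    npos[i] = r.n_pos;
    depth[i] = r.depth;
    q1[i] = r.n > 0 ? (double)r.n_pos / (double)r.n : 0.0;
  }
  return List::create(
    _["feature"] = feature, _["threshold"] = threshold,
    _["left"] = left, _["right"] = right,
    _["n"] = nvec, _["n_pos"] = npos, _["depth"] = depth, _["q1"] = q1);
}

static inline int tree_leaf(const IntegerVector &feature,
                            const NumericVector &threshold,
                            const IntegerVector &left,
                            const IntegerVector &right,
                            const NumericMatrix &X, int row) {
  int node = 0;
  while (feature[node] != NA_INTEGER) {
    int f = feature[node] - 1;
    node = (X(row, f) <= threshold[node]) ? left[node] - 1 : right[node] - 1;
  }
  return node;
}

// [[Rcpp::export(name = ".predict_gini_tree")]]
NumericVector predict_gini_tree(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], q1 = tree["q1"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = q1[tree_leaf(feature, threshold, left, right, X, i)];
  return out;
}

// [[Rcpp::export(name = ".predict_gini_forest")]]
NumericMatrix predict_gini_forest(List trees, NumericMatrix X) {
  const int T = trees.size(), n = X.nrow();
  NumericMatrix out(n, T);
  for (int t = 0; t < T; ++t) {
    List tree = trees[t];
    IntegerVector feature = tree["feature"], left = tree["left"],
                  right = tree["right"];
    NumericVector threshold = tree["threshold"], q1 = tree["q1"];
    for (int i = 0; i < n; ++i)
      out(i, t) = q1[tree_leaf(feature, threshold, left, right, X, i)];
  }
  return out;
}
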