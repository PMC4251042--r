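#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// From-scratch CART-style trees and a bagged forest for binary
// classification, trained by maximising information gain (bits).
//
// Determinism contract: all randomness flows from a single 64-bit seed via
// a splitmix64 stream; tree t of a forest uses an independent stream derived
// from (seed, t), so results do not depend on evaluation order.  Bounded
// draws use the multiply-shift reduction, never std::distributions (whose
// output is implementation-defined).

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t next() {
    s += 0x9E3779B97F4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform integer in [0, n)
  int below(int n) {
    return (int)(((unsigned __int128)next() * (uint64_t)n) >> 64);
  }
  // sample k distinct values from {0, ..., n-1}, returned sorted
  std::vector<int> sample_sorted(int n, int k) {
    std::vector<int> pool(n);
    for (int i = 0; i < n; ++i) pool[i] = i;
    for (int i = 0; i < k; ++i) {
      int j = i + below(n - i);
      std::swap(pool[i], pool[j]);
    }
    pool.resize(k);
    std::sort(pool.begin(), pool.end());
    return pool;
  }
};

inline double entropy2(int a, int b) {
  const int n = a + b;
  double h = 0.0;
  if (a > 0 && a < n) {
    double p = (double)a / n;
    h -= p * std::log2(p);
  }
  if (b > 0 && b < n) {
    double p = (double)b / n;
    h -= p * std::log2(p);
  }
  return h;
}

struct Node {
  int feature;       // -1 for leaf
  double threshold;  // x[feature] <= threshold goes left
  int left, right;   // 0-based node indices, -1 for leaf
  double p1;         // class-1 fraction of training samples at the node
  int n;             // training samples at the node
};

// Grows one tree using presorted per-feature index lists: each feature's
// sample indices are sorted once at the root, and a node split partitions
// every feature's list stably into the children, so no sorting happens
// below the root.  Split choice and tie-breaking are order-deterministic:
// candidate features ascending, thresholds ascending, strict improvement.
class Grower {
public:
  const double* X;  // column-major n x p
  int nrow, p;
  const int* y;
  int mtry, min_leaf, max_depth;  // max_depth < 0 means unlimited
  bool per_split;
  std::vector<int> avail;  // features available to this tree (sorted)
  Rng* rng;
  std::vector<Node> nodes;

  // ord[a] holds the node's sample indices sorted by feature avail[a]
  int grow(std::vector<std::vector<int> >& ord, int depth) {
    const int n = (int)ord[0].size();
    int c1 = 0;
    for (int i = 0; i < n; ++i) c1 += y[ord[0][i]];

    const int id = (int)nodes.size();
    Node nd;
    nd.feature = -1;
    nd.threshold = 0.0;
    nd.left = nd.right = -1;
    nd.p1 = (double)c1 / n;
    nd.n = n;
    nodes.push_back(nd);

    const bool can_split = c1 > 0 && c1 < n && n >= 2 * min_leaf &&
                           (max_depth < 0 || depth < max_depth);
    if (!can_split) return id;

    std::vector<int> cand;  // positions into avail/ord
    if (per_split && mtry < (int)avail.size()) {
      cand = rng->sample_sorted((int)avail.size(), mtry);
    } else {
      cand.resize(avail.size());
      for (size_t i = 0; i < avail.size(); ++i) cand[i] = (int)i;
    }

    const double h_parent = entropy2(n - c1, c1);
    double best_gain = 0.0, best_thr = 0.0;
    int best_f = -1, best_a = -1;

    for (size_t ci = 0; ci < cand.size(); ++ci) {
      const int a = cand[ci];
      const int f = avail[a];
      const double* col = X + (size_t)f * nrow;
      const std::vector<int>& o = ord[a];
      int l1 = 0;
      for (int k = 0; k < n - 1; ++k) {
        l1 += y[o[k]];
        const double vk = col[o[k]], vk1 = col[o[k + 1]];
        if (vk >= vk1) continue;  // not a value boundary
        const double thr = 0.5 * (vk + vk1);
        if (!(vk < thr && thr < vk1)) continue;  // fp midpoint guard
        const int nl = k + 1, nr = n - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        const int r1 = c1 - l1;
        const double h = (nl * entropy2(nl - l1, l1) +
                          nr * entropy2(nr - r1, r1)) / n;
        const double gain = h_parent - h;
        // strict > keeps the first (lowest feature, lowest threshold) optimum
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_a = a;
          best_thr = thr;
        }
      }
    }

    if (best_f < 0 || best_gain <= 1e-12) return id;  // no informative split

    // stable partition of every feature's sorted list
    const double* bcol = X + (size_t)best_f * nrow;
    const size_t na = avail.size();
    std::vector<std::vector<int> > lord(na), rord(na);
    int nl = 0;
    {
      const std::vector<int>& o = ord[best_a];
      for (int i = 0; i < n; ++i) nl += (bcol[o[i]] <= best_thr);
    }
    for (size_t a = 0; a < na; ++a) {
      lord[a].reserve(nl);
      rord[a].reserve(n - nl);
      const std::vector<int>& o = ord[a];
      for (int i = 0; i < n; ++i) {
        const int s = o[i];
        if (bcol[s] <= best_thr) lord[a].push_back(s);
        else rord[a].push_back(s);
      }
    }
    { std::vector<std::vector<int> > tmp; tmp.swap(ord); }  // free parent lists

    nodes[id].feature = best_f;
    nodes[id].threshold = best_thr;
    const int lid = grow(lord, depth + 1);
    nodes[id].left = lid;
    { std::vector<std::vector<int> > tmp; tmp.swap(lord); }
    const int rid = grow(rord, depth + 1);
    nodes[id].right = rid;
    return id;
  }
};

List tree_to_list(const std::vector<Node>& nodes) {
  const int k = (int)nodes.size();
  IntegerVector feature(k), left(k), right(k), nvec(k);
  NumericVector threshold(k), p1(k);
  for (int i = 0; i < k; ++i) {
    feature[i] = nodes[i].feature < 0 ? NA_INTEGER : nodes[i].feature + 1;
    threshold[i] = nodes[i].threshold;
    left[i] = nodes[i].left < 0 ? NA_INTEGER : nodes[i].left + 1;
    right[i] = nodes[i].right < 0 ? NA_INTEGER : nodes[i].right + 1;
    p1[i] = nodes[i].p1;
    nvec[i] = nodes[i].n;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right, _["p1"] = p1,
                      _["n"] = nvec);
}

uint64_t stream_seed(double seed, int t) {
  // mix the user seed, then offset per tree; splitmix64 scrambles further
  uint64_t base = (uint64_t)(int64_t)seed;
  base = (base ^ 0xD1B54A32D192ED03ULL) * 0x2545F4914F6CDD1DULL;
  return base + (uint64_t)(t + 1) * 0x9E3779B97F4A7C15ULL;
}

std::vector<Node> train_one(const NumericMatrix& X, const IntegerVector& y,
                            int mtry, int min_leaf, int max_depth,
                            bool per_split, bool bootstrap, Rng& rng) {
  const int n = X.nrow(), p = X.ncol();
  Grower g;
  g.X = REAL(X);
  g.nrow = n;
  g.p = p;
  g.y = INTEGER(y);
  g.mtry = mtry;
  g.min_leaf = min_leaf;
  g.max_depth = max_depth;
  g.per_split = per_split;
  g.rng = &rng;
  if (per_split || mtry >= p) {
    g.avail.resize(p);
    for (int i = 0; i < p; ++i) g.avail[i] = i;
  } else {
    g.avail = rng.sample_sorted(p, mtry);  // fixed per-tree subspace
  }
  std::vector<int> idx(n);
  if (bootstrap) {
    for (int i = 0; i < n; ++i) idx[i] = rng.below(n);
  } else {
    for (int i = 0; i < n; ++i) idx[i] = i;
  }
  // presort the sample once per available feature (stable, so deterministic)
  std::vector<std::vector<int> > ord(g.avail.size());
  for (size_t a = 0; a < g.avail.size(); ++a) {
    const double* col = REAL(X) + (size_t)g.avail[a] * n;
    ord[a] = idx;
    std::stable_sort(ord[a].begin(), ord[a].end(),
                     [col](int i, int j) { return col[i] < col[j]; });
  }
  g.grow(ord, 0);
  return g.nodes;
}

}  // namespace

// [[Rcpp::export]]
List train_tree_cpp(NumericMatrix X, IntegerVector y, int mtry, int min_leaf,
                    int max_depth, bool per_split, bool bootstrap,
                    double seed) {
  if (X.nrow() < 1) stop("cannot train a tree on zero samples");
  Rng rng(stream_seed(seed, 0));
  return tree_to_list(
      train_one(X, y, mtry, min_leaf, max_depth, per_split, bootstrap, rng));
}

// [[Rcpp::export]]
List train_forest_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                      int min_leaf, int max_depth, bool per_split,
                      bool bootstrap, double seed) {
  if (X.nrow() < 1) stop("cannot train a forest on zero samples");
  List out(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    Rng rng(stream_seed(seed, t));
    out[t] = tree_to_list(
        train_one(X, y, mtry, min_leaf, max_depth, per_split, bootstrap, rng));
  }
  return out;
}

static void predict_tree_into(const List& tree, const NumericMatrix& X,
                              std::vector<double>& acc) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], p1 = tree["p1"];
  const int n = X.nrow();
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] != NA_INTEGER) {
      const double x = X(i, feature[node] - 1);
      node = (x <= threshold[node]) ? left[node] - 1 : right[node] - 1;
    }
    acc[i] += p1[node];
  }
}

// [[Rcpp::export]]
NumericVector predict_tree_cpp(List tree, NumericMatrix X) {
  std::vector<double> acc(X.nrow(), 0.0);
  predict_tree_into(tree, X, acc);
  return wrap(acc);
}

// [[Rcpp::export]]
NumericVector predict_forest_cpp(List trees, NumericMatrix X) {
  const int T = trees.size();
  if (T < 1) stop("empty forest");
  std::vector<double> acc(X.nrow(), 0.0);
  for (int t = 0; t < T; ++t) predict_tree_into(trees[t], X, acc);
  NumericVector out = wrap(acc);
  return out / (double)T;
}
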