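// Bagged CART regression forest with out-of-bag scoring and TreeSHAP
// attributions. Self-contained: trees are returned as plain R lists of
// parallel arrays so fitted models serialize with saveRDS and survive
// across sessions without external pointers.
//
// RNG is a Mersenne twister driven only by the user seed; bounded draws
// use modulo reduction so results do not depend on the standard
// library's distribution implementations.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct TreeArrays {
  std::vector<int> feature;   // -1 for leaves
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> value;  // mean response of in-node bootstrap samples
  std::vector<double> cover;  // number of in-node bootstrap samples

  int add_node(double val, double cov) {
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(val);
    cover.push_back(cov);
    return static_cast<int>(feature.size()) - 1;
  }
};

inline std::uint32_t draw(std::mt19937 &rng, std::uint32_t n) {
  return rng() % n;
}

struct SplitResult {
  bool found = false;
  int feature = -1;
  double threshold = 0.0;
  double score = -1.0; // sum_l^2/n_l + sum_r^2/n_r, to be maximized
};

// Binary (0/1) columns -- the bulk of a fingerprint feature space --
// are bit-packed column-major so the whole design matrix stays
// cache-resident during split search.
struct BinaryPack {
  int n = 0, wpc = 0;                // samples, 64-bit words per column
  std::vector<std::uint64_t> words;  // wpc words per packed column
  std::vector<int> slot;             // column -> packed slot or -1
};

inline bool bit_at(const std::uint64_t *w, int i) {
  return (w[i >> 6] >> (i & 63)) & 1ULL;
}

BinaryPack pack_binary(const NumericMatrix &X) {
  const int n = X.nrow(), p = X.ncol();
  BinaryPack bp;
  bp.n = n;
  bp.wpc = (n + 63) / 64;
  bp.slot.assign(p, -1);
  int n_bin = 0;
  for (int j = 0; j < p; ++j) {
    bool binary = true;
    for (int i = 0; i < n; ++i) {
      const double v = X(i, j);
      if (v != 0.0 && v != 1.0) { binary = false; break; }
    }
    if (binary) bp.slot[j] = n_bin++;
  }
  bp.words.assign(static_cast<size_t>(n_bin) * bp.wpc, 0ULL);
  for (int j = 0; j < p; ++j) {
    if (bp.slot[j] < 0) continue;
    std::uint64_t *w = &bp.words[static_cast<size_t>(bp.slot[j]) * bp.wpc];
    for (int i = 0; i < n; ++i) {
      if (X(i, j) == 1.0) w[i >> 6] |= (1ULL << (i & 63));
    }
  }
  return bp;
}

// Split search for a packed binary column: single threshold at 0.5.
void best_split_binary(const std::uint64_t *wcol, const std::vector<int> &idx,
                       int start, int end, const double *ybuf, double sum,
                       int min_leaf, int feat, SplitResult &best) {
  const int m = end - start;
  int n1 = 0;
  double s1 = 0.0;
  for (int i = start; i < end; ++i) { // branchless accumulation
    const int b = static_cast<int>(bit_at(wcol, idx[i]));
    n1 += b;
    s1 += b * ybuf[i - start];
  }
  const int n0 = m - n1;
  if (n0 < min_leaf || n1 < min_leaf) return;
  const double s0 = sum - s1;
  const double score = s0 * s0 / n0 + s1 * s1 / n1;
  if (score > best.score) {
    best.found = true;
    best.feature = feat;
    best.threshold = 0.5;
    best.score = score;
  }
}

// General numeric column: gather, sort, scan.
void best_split_numeric(const double *xcol, const double *y,
                        const std::vector<int> &idx, int start, int end,
                        int min_leaf, int feat, SplitResult &best,
                        std::vector<std::pair<double, double>> &buf) {
  const int m = end - start;
  buf.clear();
  for (int i = start; i < end; ++i) {
    buf.emplace_back(xcol[idx[i]], y[idx[i]]);
  }
  std::sort(buf.begin(), buf.end());
  if (buf.front().first == buf.back().first) return; // constant feature
  double total = 0.0;
  for (const auto &p : buf) total += p.second;
  double sl = 0.0;
  for (int i = 0; i < m - 1; ++i) {
    sl += buf[i].second;
    const int nl = i + 1, nr = m - nl;
    if (buf[i].first == buf[i + 1].first) continue; // no cut between ties
    if (nl < min_leaf) continue;
    if (nr < min_leaf) break;
    const double sr = total - sl;
    const double score = sl * sl / nl + sr * sr / nr;
    if (score > best.score) {
      best.found = true;
      best.feature = feat;
      best.threshold = 0.5 * (buf[i].first + buf[i + 1].first);
      best.score = score;
    }
  }
}

struct StackItem {
  int node, start, end, depth;
};

TreeArrays grow_tree(const NumericMatrix &X, const NumericVector &y,
                     const BinaryPack &bp, std::vector<int> idx, int mtry,
                     int min_leaf, int max_depth, std::mt19937 &rng) {
  const int p = X.ncol();
  TreeArrays tree;
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  std::vector<std::pair<double, double>> buf;
  buf.reserve(idx.size());
  std::vector<double> ybuf(idx.size());

  double s = 0.0;
  for (int i : idx) s += y[i];
  const int n = static_cast<int>(idx.size());
  int root = tree.add_node(s / n, n);

  std::vector<StackItem> stack;
  stack.push_back({root, 0, n, 0});
  while (!stack.empty()) {
    StackItem it = stack.back();
    stack.pop_back();
    const int m = it.end - it.start;
    double sum = 0.0, sumsq = 0.0;
    for (int i = it.start; i < it.end; ++i) {
      const double yi = y[idx[i]];
      ybuf[i - it.start] = yi;
      sum += yi;
      sumsq += yi * yi;
    }
    const double sse = sumsq - sum * sum / m;
    if (m < 2 * min_leaf || it.depth >= max_depth || sse <= 1e-12) continue;

    // sample mtry features without replacement (partial Fisher-Yates)
    for (int j = 0; j < mtry; ++j) {
      const int k = j + static_cast<int>(draw(rng, p - j));
      std::swap(feats[j], feats[k]);
    }
    SplitResult best;
    best.score = sum * sum / m; // parent score; any valid split must beat it
    for (int j = 0; j < mtry; ++j) {
      const int f = feats[j];
      if (bp.slot[f] >= 0) {
        best_split_binary(&bp.words[static_cast<size_t>(bp.slot[f]) * bp.wpc],
                          idx, it.start, it.end, ybuf.data(), sum, min_leaf,
                          f, best);
      } else {
        best_split_numeric(&X(0, f), &y[0], idx, it.start, it.end,
                           min_leaf, f, best, buf);
      }
    }
    if (!best.found) continue;

    // partition idx in place
    const double *xcol = &X(0, best.feature);
    int lo = it.start, hi = it.end - 1;
    while (lo <= hi) {
      if (xcol[idx[lo]] <= best.threshold) {
        ++lo;
      } else {
        std::swap(idx[lo], idx[hi]);
        --hi;
      }
    }
    const int mid = lo;
    if (mid == it.start || mid == it.end) continue; // numeric safety

    double sl = 0.0;
    for (int i = it.start; i < mid; ++i) sl += y[idx[i]];
    const int nl = mid - it.start, nr = it.end - mid;
    const int lnode = tree.add_node(sl / nl, nl);
    const int rnode = tree.add_node((sum - sl) / nr, nr);
    tree.feature[it.node] = best.feature;
    tree.threshold[it.node] = best.threshold;
    tree.left[it.node] = lnode;
    tree.right[it.node] = rnode;
    stack.push_back({lnode, it.start, mid, it.depth + 1});
    stack.push_back({rnode, mid, it.end, it.depth + 1});
  }
  return tree;
}

List tree_to_list(const TreeArrays &t) {
  return List::create(_["feature"] = IntegerVector(t.feature.begin(), t.feature.end()),
                      _["threshold"] = NumericVector(t.threshold.begin(), t.threshold.end()),
                      _["left"] = IntegerVector(t.left.begin(), t.left.end()),
                      _["right"] = IntegerVector(t.right.begin(), t.right.end()),
                      _["value"] = NumericVector(t.value.begin(), t.value.end()),
                      _["cover"] = NumericVector(t.cover.begin(), t.cover.end()));
}

double predict_tree(const IntegerVector &feature, const NumericVector &threshold,
                    const IntegerVector &left, const IntegerVector &right,
                    const NumericVector &value, const NumericMatrix &X, int row) {
  int node = 0;
  while (feature[node] >= 0) {
    node = (X(row, feature[node]) <= threshold[node]) ? left[node] : right[node];
  }
  return value[node];
}

} // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                int min_leaf, int max_depth, int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) must equal nrow(x)");
  if (n < 2) stop("need at least two samples");
  if (mtry < 1 || mtry > p) stop("mtry out of range");
  if (max_depth <= 0) max_depth = 1 << 30;

  std::mt19937 rng(static_cast<std::uint32_t>(seed));
  const BinaryPack bp = pack_binary(X);
  List trees(n_trees);
  std::vector<double> oob_sum(n, 0.0);
  std::vector<int> oob_cnt(n, 0);
  std::vector<int> inbag(n);

  for (int t = 0; t < n_trees; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      idx[i] = static_cast<int>(draw(rng, n));
      ++inbag[idx[i]];
    }
    TreeArrays tree = grow_tree(X, y, bp, std::move(idx), mtry, min_leaf,
                                max_depth, rng);
    List tl = tree_to_list(tree);
    trees[t] = tl;
    IntegerVector feature = tl["feature"];
    NumericVector threshold = tl["threshold"];
    IntegerVector left = tl["left"], right = tl["right"];
    NumericVector value = tl["value"];
    for (int i = 0; i < n; ++i) {
      if (inbag[i] == 0) {
        oob_sum[i] += predict_tree(feature, threshold, left, right, value, X, i);
        ++oob_cnt[i];
      }
    }
  }

  NumericVector oob_pred(n, NA_REAL);
  for (int i = 0; i < n; ++i) {
    if (oob_cnt[i] > 0) oob_pred[i] = oob_sum[i] / oob_cnt[i];
  }
  return List::create(_["trees"] = trees, _["oob_prediction"] = oob_pred);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int n_trees = trees.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < n_trees; ++t) {
    List tl = trees[t];
    IntegerVector feature = tl["feature"];
    NumericVector threshold = tl["threshold"];
    IntegerVector left = tl["left"], right = tl["right"];
    NumericVector value = tl["value"];
    for (int i = 0; i < n; ++i) {
      out[i] += predict_tree(feature, threshold, left, right, value, X, i);
    }
  }
  return out / static_cast<double>(n_trees);
}

// ---------------------------------------------------------------------------
// TreeSHAP (Lundberg et al.): exact Shapley values of the per-tree
// conditional-expectation value function, in polynomial time.

namespace {

struct PathElem {
  int d;       // feature index on the path (-1 for the dummy root elem)
  double z;    // fraction of "zero" (cold) paths flowing through
  double o;    // fraction of "one" (hot) paths flowing through
  double w;    // permutation weight
};

void extend_path(std::vector<PathElem> &m, double pz, double po, int pi) {
  const int l = static_cast<int>(m.size());
  m.push_back({pi, pz, po, l == 0 ? 1.0 : 0.0});
  for (int i = l - 1; i >= 0; --i) {
    m[i + 1].w += po * m[i].w * (i + 1) / static_cast<double>(l + 1);
    m[i].w = pz * m[i].w * (l - i) / static_cast<double>(l + 1);
  }
}

void unwind_path(std::vector<PathElem> &m, int i) {
  const int l = static_cast<int>(m.size()) - 1;
  const double o = m[i].o, z = m[i].z;
  double nxt = m[l].w;
  for (int j = l - 1; j >= 0; --j) {
    if (o != 0.0) {
      const double tmp = m[j].w;
      m[j].w = nxt * (l + 1) / ((j + 1) * o);
      nxt = tmp - m[j].w * z * (l - j) / static_cast<double>(l + 1);
    } else {
      m[j].w = m[j].w * (l + 1) / (z * (l - j));
    }
  }
  for (int j = i; j < l; ++j) {
    m[j].d = m[j + 1].d;
    m[j].z = m[j + 1].z;
    m[j].o = m[j + 1].o;
  }
  m.pop_back();
}

double unwound_sum(const std::vector<PathElem> &m, int i) {
  std::vector<PathElem> cp(m);
  unwind_path(cp, i);
  double s = 0.0;
  for (const auto &e : cp) s += e.w;
  return s;
}

struct TreeView {
  IntegerVector feature, left, right;
  NumericVector threshold, value, cover;
};

void tree_shap_recurse(const TreeView &t, const NumericMatrix &X, int row,
                       double *phi, std::vector<PathElem> m, int node,
                       double pz, double po, int pi) {
  extend_path(m, pz, po, pi);
  if (t.feature[node] < 0) {
    for (int i = 1; i < static_cast<int>(m.size()); ++i) {
      const double w = unwound_sum(m, i);
      phi[m[i].d] += w * (m[i].o - m[i].z) * t.value[node];
    }
    return;
  }
  const int f = t.feature[node];
  int hot = t.left[node], cold = t.right[node];
  if (!(X(row, f) <= t.threshold[node])) std::swap(hot, cold);
  double iz = 1.0, io = 1.0;
  for (int k = 1; k < static_cast<int>(m.size()); ++k) {
    if (m[k].d == f) {
      iz = m[k].z;
      io = m[k].o;
      unwind_path(m, k);
      break;
    }
  }
  const double cr = t.cover[node];
  tree_shap_recurse(t, X, row, phi, m, hot, iz * t.cover[hot] / cr, io, f);
  tree_shap_recurse(t, X, row, phi, m, cold, iz * t.cover[cold] / cr, 0.0, f);
}

} // namespace

// [[Rcpp::export(name = ".rf_shap_cpp")]]
List rf_shap_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol();
  const int n_trees = trees.size();
  NumericMatrix phi(n, p);
  double base = 0.0;
  std::vector<double> acc(p);
  for (int t = 0; t < n_trees; ++t) {
    List tl = trees[t];
    TreeView tv{tl["feature"], tl["left"], tl["right"],
                tl["threshold"], tl["value"], tl["cover"]};
    base += tv.value[0];
    for (int i = 0; i < n; ++i) {
      std::fill(acc.begin(), acc.end(), 0.0);
      std::vector<PathElem> m;
      tree_shap_recurse(tv, X, i, acc.data(), m, 0, 1.0, 1.0, -1);
      for (int j = 0; j < p; ++j) phi(i, j) += acc[j];
    }
  }
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) phi(i, j) /= n_trees;
  }
  return List::create(_["phi"] = phi,
                      _["base_value"] = base / n_trees);
}
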