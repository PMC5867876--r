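// Small deterministic CART-style classification tree used by the Monte
// Carlo feature-selection stage. Split criterion is base-2 information
// gain; numeric thresholds sit at midpoints between consecutive distinct
// observed values; nodes are grown until purity or fewer than `min_split`
// samples; no pruning. Ties in gain resolve to the lowest threshold value
// (column-order invariant), then the lowest feature index. Every internal
// node's gain and sample count are recorded so the caller can accumulate
// per-feature relative importance.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

static double entropy_bits(const std::vector<int>& counts, int n) {
  if (n <= 0) return 0.0;
  double h = 0.0;
  for (int c : counts) {
    if (c > 0) {
      double p = static_cast<double>(c) / n;
      h -= p * std::log2(p);
    }
  }
  return h;
}

struct NodeWork {
  int id;
  std::vector<int> idx;
};

// [[Rcpp::export]]
List build_tree_cpp(NumericMatrix X, IntegerVector y, int n_class,
                    int min_split) {
  const int n = X.nrow(), m = X.ncol();
  std::vector<int> feature, left, right, pred, n_node;
  std::vector<double> threshold, gain;

  auto new_node = [&]() {
    feature.push_back(-1);
    threshold.push_back(NA_REAL);
    gain.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    pred.push_back(-1);
    n_node.push_back(0);
    return static_cast<int>(feature.size()) - 1;
  };

  std::vector<NodeWork> stack;
  {
    NodeWork root;
    root.id = new_node();
    root.idx.resize(n);
    for (int i = 0; i < n; ++i) root.idx[i] = i;
    stack.push_back(std::move(root));
  }

  std::vector<std::pair<double, int>> sv;  // (value, label) sorted per feature

  while (!stack.empty()) {
    NodeWork w = std::move(stack.back());
    stack.pop_back();
    const int id = w.id;
    const int nn = static_cast<int>(w.idx.size());
    n_node[id] = nn;

    std::vector<int> counts(n_class, 0);
    for (int i : w.idx) counts[y[i]]++;
    int best_class = 0;
    for (int k = 1; k < n_class; ++k)
      if (counts[k] > counts[best_class]) best_class = k;  // tie -> lowest code
    pred[id] = best_class;

    int present = 0;
    for (int c : counts) if (c > 0) ++present;
    if (present <= 1 || nn < min_split) continue;  // leaf

    const double h_parent = entropy_bits(counts, nn);
    double best_gain = 0.0, best_thr = 0.0;
    int best_feat = -1;

    for (int j = 0; j < m; ++j) {
      sv.clear();
      sv.reserve(nn);
      for (int i : w.idx) sv.emplace_back(X(i, j), y[i]);
      std::sort(sv.begin(), sv.end());
      std::vector<int> lc(n_class, 0);
      int nl = 0;
      for (int r = 0; r + 1 < nn; ++r) {
        lc[sv[r].second]++;
        ++nl;
        if (sv[r].first == sv[r + 1].first) continue;  // not a boundary
        std::vector<int> rc(n_class);
        for (int k = 0; k < n_class; ++k) rc[k] = counts[k] - lc[k];
        const int nr = nn - nl;
        const double g = h_parent -
          (static_cast<double>(nl) / nn) * entropy_bits(lc, nl) -
          (static_cast<double>(nr) / nn) * entropy_bits(rc, nr);
        // ties in gain (common in small nodes, where gain depends only on
        // label counts) resolve to the smaller threshold so the choice
        // does not depend on column order; feature index is the last
        // resort only
        const double thr = (sv[r].first + sv[r + 1].first) / 2.0;
        if (g > best_gain ||
            (best_feat >= 0 && g == best_gain && thr < best_thr)) {
          best_gain = g;
          best_feat = j;
          best_thr = thr;
        }
      }
    }

    if (best_feat < 0 || best_gain <= 0.0) continue;  // leaf

    feature[id] = best_feat;
    threshold[id] = best_thr;
    gain[id] = best_gain;

    NodeWork wl, wr;
    for (int i : w.idx) {
      if (X(i, best_feat) <= best_thr) wl.idx.push_back(i);
      else wr.idx.push_back(i);
    }
    wl.id = new_node();
    wr.id = new_node();
    left[id] = wl.id;
    right[id] = wr.id;
    stack.push_back(std::move(wr));
    stack.push_back(std::move(wl));
  }

  return List::create(
    _["feature"] = wrap(feature), _["threshold"] = wrap(threshold),
    _["gain"] = wrap(gain), _["left"] = wrap(left), _["right"] = wrap(right),
    _["pred"] = wrap(pred), _["n_node"] = wrap(n_node),
    _["n_tree"] = n);
}

// [[Rcpp::export]]
IntegerVector predict_tree_cpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"], pred = tree["pred"];
  NumericVector threshold = tree["threshold"];
  const int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    }
    out[i] = pred[node];
  }
  return out;
}
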