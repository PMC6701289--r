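// Binary classification trees for Monte Carlo feature selection.
//
// Splits maximize Shannon information gain (log2), no pruning, minimum leaf
// size fixed by the caller.  Growing is fully deterministic: features are
// scanned in column order, candidate thresholds (midpoints of consecutive
// distinct sorted values) in ascending order, and only strict improvements
// replace the incumbent split.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static double entropy_bits(const std::vector<int>& counts, int n) {
  if (n == 0) return 0.0;
  double h = 0.0;
  for (size_t c = 0; c < counts.size(); ++c) {
    if (counts[c] > 0) {
      double p = (double)counts[c] / n;
      h -= p * std::log2(p);
    }
  }
  return h;
}

struct NodeRec {
  int feature;      // 0-based column of X, -1 for leaf
  double threshold; // go left if x <= threshold
  double ig;        // information gain of the split (bits)
  int n_node;       // training samples reaching the node
  int left, right;  // child ids, -1 for leaf
  int pred;         // majority class (0-based), ties -> lowest class index
};

// [[Rcpp::export(name = ".grow_tree_cpp")]]
List grow_tree_cpp(NumericMatrix X, IntegerVector y, int n_classes,
                   int min_leaf) {
  const int n = X.nrow(), m = X.ncol();
  std::vector<NodeRec> nodes;
  // stack of (node id, sample indices)
  std::vector<std::pair<int, std::vector<int> > > stack;
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  nodes.push_back(NodeRec());
  stack.push_back(std::make_pair(0, all));

  std::vector<int> cnt(n_classes), cntL(n_classes), cntR(n_classes);

  while (!stack.empty()) {
    int id = stack.back().first;
    std::vector<int> idx = stack.back().second;
    stack.pop_back();
    int nn = (int)idx.size();

    std::fill(cnt.begin(), cnt.end(), 0);
    for (int k = 0; k < nn; ++k) cnt[y[idx[k]]]++;
    int best_class = 0;
    for (int c = 1; c < n_classes; ++c)
      if (cnt[c] > cnt[best_class]) best_class = c;
    double h_parent = entropy_bits(cnt, nn);

    NodeRec& nd = nodes[id];
    nd.n_node = nn;
    nd.pred = best_class;
    nd.feature = -1; nd.threshold = NA_REAL; nd.ig = 0.0;
    nd.left = -1; nd.right = -1;

    if (nn < 2 * min_leaf || h_parent <= 0.0) continue;

    // best split search
    double best_ig = 0.0, best_thr = 0.0;
    int best_feat = -1;
    std::vector<std::pair<double, int> > vals(nn);
    for (int j = 0; j < m; ++j) {
      for (int k = 0; k < nn; ++k)
        vals[k] = std::make_pair(X(idx[k], j), y[idx[k]]);
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      std::fill(cntL.begin(), cntL.end(), 0);
      for (int c = 0; c < n_classes; ++c) cntR[c] = cnt[c];
      int nL = 0;
      for (int k = 0; k < nn - 1; ++k) {
        cntL[vals[k].second]++; cntR[vals[k].second]--; nL++;
        if (vals[k].first == vals[k + 1].first) continue;
        int nR = nn - nL;
        if (nL < min_leaf || nR < min_leaf) continue;
        double ig = h_parent -
          ((double)nL / nn) * entropy_bits(cntL, nL) -
          ((double)nR / nn) * entropy_bits(cntR, nR);
        if (ig > best_ig + 1e-12) {
          best_ig = ig;
          best_feat = j;
          best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
        }
      }
    }
    if (best_feat < 0) continue;

    std::vector<int> li, ri;
    for (int k = 0; k < nn; ++k) {
      if (X(idx[k], best_feat) <= best_thr) li.push_back(idx[k]);
      else ri.push_back(idx[k]);
    }
    int lid = (int)nodes.size(); nodes.push_back(NodeRec());
    int rid = (int)nodes.size(); nodes.push_back(NodeRec());
    nodes[id].feature = best_feat;
    nodes[id].threshold = best_thr;
    nodes[id].ig = best_ig;
    nodes[id].left = lid;
    nodes[id].right = rid;
    stack.push_back(std::make_pair(lid, li));
    stack.push_back(std::make_pair(rid, ri));
  }

  int nn = (int)nodes.size();
  IntegerVector feature(nn), n_node(nn), left(nn), right(nn), pred(nn);
  NumericVector threshold(nn), ig(nn);
  for (int i = 0; i < nn; ++i) {
    feature[i] = nodes[i].feature < 0 ? NA_INTEGER : nodes[i].feature + 1;
    threshold[i] = nodes[i].threshold;
    ig[i] = nodes[i].ig;
    n_node[i] = nodes[i].n_node;
    left[i] = nodes[i].left < 0 ? NA_INTEGER : nodes[i].left + 1;
    right[i] = nodes[i].right < 0 ? NA_INTEGER : nodes[i].right + 1;
    pred[i] = nodes[i].pred;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["ig"] = ig, _["n_node"] = n_node, _["left"] = left,
                      _["right"] = right, _["pred"] = pred);
}

// [[Rcpp::export(name = ".predict_tree_cpp")]]
IntegerVector predict_tree_cpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"],
                pred = tree["pred"];
  const int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] != NA_INTEGER) {
      int j = feature[node] - 1;
      node = (X(i, j) <= threshold[node] ? left[node] : right[node]) - 1;
    }
    out[i] = pred[node];
  }
  return out;
}
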