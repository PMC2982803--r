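#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Build children lists for an unrooted edge list rooted at `root`.
// Nodes are 1-based; returns postorder node sequence and parent array.
static void root_tree(const IntegerMatrix& edge, int n_nodes, int root,
                      std::vector<int>& parent, std::vector<int>& postorder) {
  std::vector<std::vector<int> > adj(n_nodes + 1);
  for (int i = 0; i < edge.nrow(); ++i) {
    adj[edge(i, 0)].push_back(edge(i, 1));
    adj[edge(i, 1)].push_back(edge(i, 0));
  }
  parent.assign(n_nodes + 1, 0);
  postorder.clear();
  postorder.reserve(n_nodes);
  std::vector<int> stack;
  std::vector<int> order;
  order.reserve(n_nodes);
  stack.push_back(root);
  parent[root] = -1;
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    order.push_back(v);
    for (size_t k = 0; k < adj[v].size(); ++k) {
      int w = adj[v][k];
      if (w != parent[v]) {
        parent[w] = v;
        stack.push_back(w);
      }
    }
  }
  for (int i = (int)order.size() - 1; i >= 0; --i) postorder.push_back(order[i]);
}

// Minimum total transition cost of all characters on an unrooted tree
// (Sankoff dynamic programming). `states` is n_tips x n_char with integer
// states 0..S-1; `tip_row` maps node id -> 1-based row of `states` (0 for
// internal nodes). Tree is rooted arbitrarily at `root` (any internal node);
// the score does not depend on this choice.
// [[Rcpp::export(name = ".sankoff_total_cpp")]]
double sankoff_total_cpp(IntegerMatrix edge, int n_nodes, int root,
                         IntegerVector tip_row, IntegerMatrix states,
                         NumericMatrix cost) {
  const int S = cost.nrow();
  const int C = states.ncol();
  const double INF = 1e300;
  std::vector<int> parent, postorder;
  root_tree(edge, n_nodes, root, parent, postorder);
  std::vector<double> dp((n_nodes + 1) * S);
  double total = 0.0;
  for (int ch = 0; ch < C; ++ch) {
    for (size_t idx = 0; idx < postorder.size(); ++idx) {
      int v = postorder[idx];
      double* dv = &dp[v * S];
      int row = tip_row[v - 1];
      if (row > 0) {
        int st = states(row - 1, ch);
        for (int s = 0; s < S; ++s) dv[s] = (s == st) ? 0.0 : INF;
      } else {
        for (int s = 0; s < S; ++s) dv[s] = 0.0;
      }
    }
    // accumulate children into parents (postorder guarantees children first)
    for (size_t idx = 0; idx < postorder.size(); ++idx) {
      int v = postorder[idx];
      int p = parent[v];
      if (p <= 0) continue;
      double* dv = &dp[v * S];
      double* dpnt = &dp[p * S];
      for (int s = 0; s < S; ++s) {
        double best = INF;
        for (int t = 0; t < S; ++t) {
          double c = cost(s, t) + dv[t];
          if (c < best) best = c;
        }
        dpnt[s] += best;
      }
    }
    double best = INF;
    double* dr = &dp[root * S];
    for (int s = 0; s < S; ++s) if (dr[s] < best) best = dr[s];
    total += best;
  }
  return total;
}

// Sankoff DP plus a deterministic minimal-cost backtrace. Root state is the
// lowest-index state attaining the minimum; each child takes the lowest-index
// state minimising cost(parent_state, s) + subtree cost. Returns, for each
// input edge row, the total number of state changes (summed |cost| units)
// assigned to that branch over all characters.
// [[Rcpp::export(name = ".sankoff_branch_changes_cpp")]]
NumericVector sankoff_branch_changes_cpp(IntegerMatrix edge, int n_nodes,
                                         int root, IntegerVector tip_row,
                                         IntegerMatrix states,
                                         NumericMatrix cost) {
  const int S = cost.nrow();
  const int C = states.ncol();
  const double INF = 1e300;
  std::vector<int> parent, postorder;
  root_tree(edge, n_nodes, root, parent, postorder);
  std::map<std::pair<int, int>, int> edge_row;
  for (int i = 0; i < edge.nrow(); ++i) {
    edge_row[std::make_pair(edge(i, 0), edge(i, 1))] = i;
    edge_row[std::make_pair(edge(i, 1), edge(i, 0))] = i;
  }
  NumericVector out(edge.nrow());
  std::vector<double> dp((n_nodes + 1) * S);
  std::vector<int> assigned(n_nodes + 1);
  for (int ch = 0; ch < C; ++ch) {
    for (size_t idx = 0; idx < postorder.size(); ++idx) {
      int v = postorder[idx];
      double* dv = &dp[v * S];
      int row = tip_row[v - 1];
      if (row > 0) {
        int st = states(row - 1, ch);
        for (int s = 0; s < S; ++s) dv[s] = (s == st) ? 0.0 : INF;
      } else {
        for (int s = 0; s < S; ++s) dv[s] = 0.0;
      }
    }
    for (size_t idx = 0; idx < postorder.size(); ++idx) {
      int v = postorder[idx];
      int p = parent[v];
      if (p <= 0) continue;
      double* dv = &dp[v * S];
      double* dpnt = &dp[p * S];
      for (int s = 0; s < S; ++s) {
        double best = INF;
        for (int t = 0; t < S; ++t) {
          double c = cost(s, t) + dv[t];
          if (c < best) best = c;
        }
        dpnt[s] += best;
      }
    }
    // preorder backtrace (reverse of postorder visits parents first)
    for (int idx = (int)postorder.size() - 1; idx >= 0; --idx) {
      int v = postorder[idx];
      double* dv = &dp[v * S];
      if (parent[v] <= 0) {
        int bs = 0;
        for (int s = 1; s < S; ++s) if (dv[s] < dv[bs]) bs = s;
        assigned[v] = bs;
      } else {
        int ps = assigned[parent[v]];
        int bs = 0;
        double best = INF;
        for (int s = 0; s < S; ++s) {
          double c = cost(ps, s) + dv[s];
          if (c < best) { best = c; bs = s; }
        }
        assigned[v] = bs;
        out[edge_row[std::make_pair(parent[v], v)]] += cost(ps, bs);
      }
    }
  }
  return out;
}

// Percent identity between two rows of a multiple alignment, excluding
// columns inside either row's terminal-gap runs; columns where both rows are
// gapped are not compared; a column where exactly one row is gapped counts as
// one difference. Rows are integer-coded (0 = gap). Returns (identity,
// n_compared); identity is NA when no columns are comparable.
// [[Rcpp::export(name = ".identity_one_cpp")]]
NumericVector identity_one_cpp(IntegerVector a, IntegerVector b,
                               int first_a, int last_a, int first_b,
                               int last_b) {
  int lo = std::max(first_a, first_b);
  int hi = std::min(last_a, last_b);
  int match = 0, comp = 0;
  for (int c = lo - 1; c <= hi - 1; ++c) {
    int x = a[c], y = b[c];
    if (x == 0 && y == 0) continue;
    ++comp;
    if (x == y) ++match;
  }
  NumericVector res(2);
  if (comp == 0) {
    res[0] = NA_REAL;
    res[1] = 0;
  } else {
    res[0] = 100.0 * match / comp;
    res[1] = comp;
  }
  return res;
}

// All pairs of alignment rows with identity >= threshold (percent), using the
// rules of identity_one_cpp. `first`/`last` give each row's non-terminal-gap
// span (1-based columns). Early abort once the mismatch count alone rules out
// reaching the threshold. Returns a list (i, j, identity) of 1-based indices.
// [[Rcpp::export(name = ".identity_pairs_cpp")]]
List identity_pairs_cpp(IntegerMatrix rows, IntegerVector first,
                        IntegerVector last, double threshold) {
  const int n = rows.nrow();
  std::vector<int> vi, vj;
  std::vector<double> vid;
  const double miss_frac = 1.0 - threshold / 100.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int lo = std::max(first[i], first[j]);
      int hi = std::min(last[i], last[j]);
      if (lo > hi) continue;
      double max_mm = miss_frac * (hi - lo + 1);
      int match = 0, comp = 0, mm = 0;
      bool aborted = false;
      for (int c = lo - 1; c <= hi - 1; ++c) {
        int x = rows(i, c), y = rows(j, c);
        if (x == 0 && y == 0) continue;
        ++comp;
        if (x == y) {
          ++match;
        } else if (++mm > max_mm) {
          aborted = true;
          break;
        }
      }
      if (aborted || comp == 0) continue;
      double id = 100.0 * match / comp;
      if (id >= threshold) {
        vi.push_back(i + 1);
        vj.push_back(j + 1);
        vid.push_back(id);
      }
    }
  }
  return List::create(_["i"] = wrap(vi), _["j"] = wrap(vj),
                      _["identity"] = wrap(vid));
}

// Longest contiguous window whose terminal bases both have error probability
// <= max_error and whose mean error probability <= max_error. Ties broken by
// earliest start. Returns 1-based (start, end); (0, -1) when no base
// qualifies.
// [[Rcpp::export(name = ".trim_bounds_cpp")]]
IntegerVector trim_bounds_cpp(NumericVector err, double max_error) {
  const int n = err.size();
  std::vector<double> cum(n + 1, 0.0);
  for (int i = 0; i < n; ++i) cum[i + 1] = cum[i] + err[i];
  // fast path: whole read qualifies
  if (n > 0 && err[0] <= max_error && err[n - 1] <= max_error &&
      cum[n] <= max_error * n) {
    return IntegerVector::create(1, n);
  }
  std::vector<int> ok;
  for (int i = 0; i < n; ++i) if (err[i] <= max_error) ok.push_back(i);
  int best_len = 0, best_start = 0, best_end = -1;
  for (size_t a = 0; a < ok.size(); ++a) {
    int i = ok[a];
    for (int b = (int)ok.size() - 1; b >= (int)a; --b) {
      int j = ok[b];
      int len = j - i + 1;
      if (len <= best_len) break;
      if (cum[j + 1] - cum[i] <= max_error * len) {
        best_len = len;
        best_start = i + 1;
        best_end = j + 1;
        break;
      }
    }
  }
  return IntegerVector::create(best_start, best_end);
}
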