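#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Node indices are 1-based on the R side; converted to 0-based here.
// `inc` is the binary gene-by-case incidence matrix with one row per
// network node (zero rows for nodes without expression evidence).

static inline void add_counts(const IntegerMatrix& inc, int v,
                              std::vector<int>& counts) {
  int m = inc.ncol();
  for (int u = 0; u < m; ++u) counts[u] += inc(v, u);
}

static inline int n_covered(const std::vector<int>& counts, int k) {
  int ok = 0;
  for (size_t u = 0; u < counts.size(); ++u)
    if (counts[u] >= k) ++ok;
  return ok;
}

// Smallest radius r (<= cap) such that the r-neighborhood of `root`
// contains a feasible (k,l)-cover, taking the whole neighborhood as the
// candidate cover. The counting array over cases is updated level by
// level; the BFS halts once the level exceeds `cap` (cap < 0: no cap).
// Returns -1 when no radius <= cap is feasible.
// [[Rcpp::export]]
int cpp_min_radius(List adj, IntegerMatrix inc, int k, int l,
                   int root, int cap) {
  int n = adj.size(), m = inc.ncol();
  int need = m - l;
  if (need <= 0) return 0;
  std::vector<char> seen(n, 0);
  std::vector<int> counts(m, 0), frontier, nxt;
  seen[root - 1] = 1;
  frontier.push_back(root - 1);
  add_counts(inc, root - 1, counts);
  int level = 0;
  while (true) {
    if (n_covered(counts, k) >= need) return level;
    if (cap >= 0 && level >= cap) return -1;
    nxt.clear();
    for (size_t i = 0; i < frontier.size(); ++i) {
      IntegerVector nb = adj[frontier[i]];
      for (int j = 0; j < nb.size(); ++j) {
        int w = nb[j] - 1;
        if (!seen[w]) {
          seen[w] = 1;
          nxt.push_back(w);
          add_counts(inc, w, counts);
        }
      }
    }
    if (nxt.empty()) return -1;  // component exhausted
    frontier.swap(nxt);
    ++level;
  }
}

// Scan every node as a candidate root, keeping a running minimum radius
// as the BFS cap for subsequent roots. Returns r_min (-1 if no root is
// feasible) and the 1-based argmin root set.
// [[Rcpp::export]]
List cpp_radius_scan(List adj, IntegerMatrix inc, int k, int l) {
  int n = adj.size();
  int best = -1;
  std::vector<int> vmin;
  for (int v = 1; v <= n; ++v) {
    int cap = (best >= 0) ? best : -1;
    int r = cpp_min_radius(adj, inc, k, l, v, cap);
    if (r < 0) continue;
    if (best < 0 || r < best) {
      best = r;
      vmin.assign(1, v);
    } else if (r == best) {
      vmin.push_back(v);
    }
  }
  return List::create(_["r_min"] = best,
                      _["v_min"] = IntegerVector(vmin.begin(), vmin.end()));
}

// All nodes within graph distance <= r of root (1-based, includes root).
// [[Rcpp::export]]
IntegerVector cpp_neighborhood(List adj, int root, int r) {
  int n = adj.size();
  std::vector<char> seen(n, 0);
  std::vector<int> out, frontier, nxt;
  seen[root - 1] = 1;
  out.push_back(root);
  frontier.push_back(root - 1);
  for (int level = 0; level < r; ++level) {
    nxt.clear();
    for (size_t i = 0; i < frontier.size(); ++i) {
      IntegerVector nb = adj[frontier[i]];
      for (int j = 0; j < nb.size(); ++j) {
        int w = nb[j] - 1;
        if (!seen[w]) {
          seen[w] = 1;
          nxt.push_back(w);
          out.push_back(w + 1);
        }
      }
    }
    if (nxt.empty()) break;
    frontier.swap(nxt);
  }
  return IntegerVector(out.begin(), out.end());
}

// Does `subset` (1-based) induce a connected subgraph?
// [[Rcpp::export]]
bool cpp_is_connected(List adj, IntegerVector subset) {
  int n = adj.size(), s = subset.size();
  if (s == 0) return false;
  if (s == 1) return true;
  std::vector<char> in_sub(n, 0), seen(n, 0);
  for (int i = 0; i < s; ++i) in_sub[subset[i] - 1] = 1;
  std::vector<int> stack;
  stack.push_back(subset[0] - 1);
  seen[subset[0] - 1] = 1;
  int reached = 1;
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    IntegerVector nb = adj[v];
    for (int j = 0; j < nb.size(); ++j) {
      int w = nb[j] - 1;
      if (in_sub[w] && !seen[w]) {
        seen[w] = 1;
        ++reached;
        stack.push_back(w);
      }
    }
  }
  return reached == s;
}

// Greedy expansion from `root` inside `allowed`. At each step the
// frontier node contributing the most new progress toward k-coverage is
// added (a node's contribution to case u counts only while u is still
// under-covered). Ties go to the larger neighbor-coverage total
// `nbr_tot`, then to the smaller lexicographic `name_rank`.
// Stops when at most l cases remain under-covered; fails when the
// frontier empties first.
// [[Rcpp::export]]
List cpp_greedy(List adj, IntegerMatrix inc, int k, int l, int root,
                IntegerVector allowed, NumericVector nbr_tot,
                IntegerVector name_rank) {
  int n = adj.size(), m = inc.ncol();
  std::vector<char> in_allowed(n, 0), in_w(n, 0), in_frontier(n, 0);
  for (int i = 0; i < allowed.size(); ++i) in_allowed[allowed[i] - 1] = 1;
  std::vector<int> counts(m, 0), frontier, cover;
  int r0 = root - 1;
  in_w[r0] = 1;
  cover.push_back(root);
  add_counts(inc, r0, counts);
  {
    IntegerVector nb = adj[r0];
    for (int j = 0; j < nb.size(); ++j) {
      int w = nb[j] - 1;
      if (in_allowed[w] && !in_w[w] && !in_frontier[w]) {
        in_frontier[w] = 1;
        frontier.push_back(w);
      }
    }
  }
  while (true) {
    int under = m - n_covered(counts, k);
    if (under <= l) {
      return List::create(_["ok"] = true,
                          _["nodes"] = IntegerVector(cover.begin(), cover.end()),
                          _["counts"] = IntegerVector(counts.begin(), counts.end()));
    }
    if (frontier.empty()) {
      return List::create(_["ok"] = false);
    }
    int best_i = -1, best_gain = -1;
    double best_tot = 0.0;
    int best_rank = 0;
    for (size_t i = 0; i < frontier.size(); ++i) {
      int v = frontier[i];
      int gain = 0;
      for (int u = 0; u < m; ++u)
        if (counts[u] < k && inc(v, u)) ++gain;
      bool take = false;
      if (gain > best_gain) take = true;
      else if (gain == best_gain) {
        if (nbr_tot[v] > best_tot) take = true;
        else if (nbr_tot[v] == best_tot && name_rank[v] < best_rank) take = true;
      }
      if (take) {
        best_i = (int)i;
        best_gain = gain;
        best_tot = nbr_tot[v];
        best_rank = name_rank[v];
      }
    }
    int v = frontier[best_i];
    frontier[best_i] = frontier.back();
    frontier.pop_back();
    in_frontier[v] = 0;
    in_w[v] = 1;
    cover.push_back(v + 1);
    add_counts(inc, v, counts);
    IntegerVector nb = adj[v];
    for (int j = 0; j < nb.size(); ++j) {
      int w = nb[j] - 1;
      if (in_allowed[w] && !in_w[w] && !in_frontier[w]) {
        in_frontier[w] = 1;
        frontier.push_back(w);
      }
    }
  }
}

// Iteratively remove nodes whose removal keeps the induced subgraph
// connected and the (k,l)-cover condition true; sweeps in lexicographic
// node order until a fixed point. Returns the reduced cover (1-based).
// [[Rcpp::export]]
IntegerVector cpp_cleanup(List adj, IntegerMatrix inc, int k, int l,
                          IntegerVector cover, IntegerVector name_rank) {
  int n = adj.size(), m = inc.ncol();
  std::vector<char> present(n, 0);
  std::vector<int> counts(m, 0);
  std::vector<int> members(cover.begin(), cover.end());
  // sweep order: lexicographic by node identifier
  std::sort(members.begin(), members.end(), [&](int a, int b) {
    return name_rank[a - 1] < name_rank[b - 1];
  });
  for (size_t i = 0; i < members.size(); ++i) {
    int v = members[i] - 1;
    if (!present[v]) {
      present[v] = 1;
      add_counts(inc, v, counts);
    }
  }
  int n_present = 0;
  for (int v = 0; v < n; ++v) n_present += present[v];
  bool changed = true;
  std::vector<int> stack;
  std::vector<char> seen(n, 0);
  while (changed) {
    changed = false;
    for (size_t i = 0; i < members.size(); ++i) {
      int v = members[i] - 1;
      if (!present[v] || n_present == 1) continue;
      // coverage after removal
      int under = 0;
      for (int u = 0; u < m; ++u)
        if (counts[u] - inc(v, u) < k) ++under;
      if (under > l) continue;
      // connectivity of the remaining nodes
      present[v] = 0;
      int start = -1;
      for (size_t j = 0; j < members.size(); ++j) {
        int w = members[j] - 1;
        if (present[w]) { start = w; break; }
      }
      std::fill(seen.begin(), seen.end(), 0);
      stack.clear();
      stack.push_back(start);
      seen[start] = 1;
      int reached = 1;
      while (!stack.empty()) {
        int x = stack.back();
        stack.pop_back();
        IntegerVector nb = adj[x];
        for (int j = 0; j < nb.size(); ++j) {
          int w = nb[j] - 1;
          if (present[w] && !seen[w]) {
            seen[w] = 1;
            ++reached;
            stack.push_back(w);
          }
        }
      }
      if (reached == n_present - 1) {
        // removal accepted
        for (int u = 0; u < m; ++u) counts[u] -= inc(v, u);
        --n_present;
        changed = true;
      } else {
        present[v] = 1;  // revert
      }
    }
  }
  std::vector<int> out;
  for (size_t i = 0; i < members.size(); ++i)
    if (present[members[i] - 1]) out.push_back(members[i]);
  return IntegerVector(out.begin(), out.end());
}
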