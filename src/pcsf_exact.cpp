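#include <Rcpp.h>
#include <vector>
#include <functional>
using namespace Rcpp;

// Exact rooted, depth-bounded, directed prize-collecting Steiner forest
// by exhaustive enumeration of parent assignments.
//
// Nodes are 0..n where 0 is the dummy root; real nodes are 1..n.
// Every real node either has no parent (excluded) or selects one of
// its incoming edges. A leaf assignment is valid when every node with
// a selected parent edge chains up to the dummy within depth D (dummy
// at depth -1, its neighbours at depth 0). The objective is the sum
// of excluded-node penalties plus selected edge costs (dummy->root
// edges carry the per-tree charge as their cost).
//
// [[Rcpp::export]]
List pcsf_exact_cpp(IntegerVector efrom, IntegerVector eto,
                    NumericVector cost, NumericVector pen,
                    int n, int D, double cap) {
  const int m = efrom.size();
  const int EXCL = -99, BAD = -100;
  std::vector<std::vector<int>> in_edges(n + 1);
  for (int e = 0; e < m; ++e) {
    if (eto[e] < 1 || eto[e] > n || efrom[e] < 0 || efrom[e] > n)
      stop("edge endpoint out of range");
    in_edges[eto[e]].push_back(e);
  }
  double combos = 1.0;
  for (int v = 1; v <= n; ++v) {
    combos *= (in_edges[v].size() + 1.0);
    if (combos > cap) stop("exact solver size cap exceeded");
  }
  double base_pen = 0.0;
  for (int v = 0; v < n; ++v) base_pen += pen[v];

  std::vector<int> choice(n + 1, -1);       // parent edge index or -1
  std::vector<int> best_choice;
  double best_obj = R_PosInf;
  int best_nedges = -1;

  std::vector<int> depth(n + 1);
  std::vector<int> state(n + 1);            // 0 unseen, 1 in progress, 2 done
  // returns false on a structural violation (cycle, dangling tail,
  // depth bound); excluded nodes are valid with depth EXCL
  std::function<bool(int)> resolve = [&](int v) -> bool {
    if (state[v] == 2) return depth[v] != BAD;
    if (state[v] == 1) { depth[v] = BAD; state[v] = 2; return false; }
    state[v] = 1;
    if (choice[v] < 0) { depth[v] = EXCL; state[v] = 2; return true; }
    int x = efrom[choice[v]];
    bool ok = (x == 0) ? true : resolve(x);
    if (!ok || (x != 0 && (depth[x] == EXCL || depth[x] == BAD))) {
      depth[v] = BAD; state[v] = 2; return false;
    }
    depth[v] = (x == 0) ? 0 : depth[x] + 1;
    if (depth[v] > D) { depth[v] = BAD; state[v] = 2; return false; }
    state[v] = 2;
    return true;
  };

  std::function<void(int)> rec = [&](int v) {
    if (v > n) {
      std::fill(state.begin(), state.end(), 0);
      depth[0] = -1; state[0] = 2;
      bool valid = true;
      for (int u = 1; u <= n && valid; ++u) valid = resolve(u);
      if (!valid) return;
      double c_sum = 0.0, inc_pen = 0.0;
      int nedges = 0;
      for (int u = 1; u <= n; ++u) {
        if (choice[u] >= 0) {
          c_sum += cost[choice[u]];
          inc_pen += pen[u - 1];
          ++nedges;
        }
      }
      double obj = base_pen - inc_pen + c_sum;
      if (obj < best_obj - 1e-12 ||
          (obj < best_obj + 1e-12 && nedges < best_nedges)) {
        best_obj = obj;
        best_nedges = nedges;
        best_choice.assign(choice.begin(), choice.end());
      }
      return;
    }
    choice[v] = -1;
    rec(v + 1);
    for (int e : in_edges[v]) {
      choice[v] = e;
      rec(v + 1);
    }
    choice[v] = -1;
  };
  rec(1);

  std::vector<int> sel;
  if (!best_choice.empty())
    for (int v = 1; v <= n; ++v)
      if (best_choice[v] >= 0) sel.push_back(best_choice[v] + 1); // 1-based
  return List::create(_["edges"] = wrap(sel), _["objective"] = best_obj);
}
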