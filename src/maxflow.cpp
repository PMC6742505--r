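#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

// s/t max-flow on a binary-MRF flow network (Dinic's algorithm), plus
// constrained re-solves on the residual graph for min-marginal energies.
//
// Node ids 0..n-1 are MRF sites; S = n, T = n + 1. Arcs are stored in pairs
// (e, e^1) so the residual of arc e is cap[e] and pushing on e credits e^1.
// Label convention: after the solve, nodes reachable from S in the residual
// graph are on the source side and take label 0; cap(S->i) is therefore the
// cost charged when i takes label 1 and cap(i->T) the cost of label 0.

static const double FLOW_EPS = 1e-11;

struct FlowGraph {
  int n;           // number of MRF nodes (terminals are n and n+1)
  int S, T;
  std::vector<int> head, to, nxt;
  std::vector<double> cap;
  std::vector<int> level, iter;

  FlowGraph(int n_nodes) : n(n_nodes), S(n_nodes), T(n_nodes + 1),
                           head(n_nodes + 2, -1) {}

  void add_arc_pair(int u, int v, double c_uv, double c_vu) {
    to.push_back(v); cap.push_back(c_uv); nxt.push_back(head[u]);
    head[u] = (int)to.size() - 1;
    to.push_back(u); cap.push_back(c_vu); nxt.push_back(head[v]);
    head[v] = (int)to.size() - 1;
  }

  bool bfs_levels(int s, int t) {
    level.assign(n + 2, -1);
    std::queue<int> q;
    level[s] = 0; q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int e = head[u]; e != -1; e = nxt[e]) {
        int v = to[e];
        if (cap[e] > FLOW_EPS && level[v] < 0) {
          level[v] = level[u] + 1;
          q.push(v);
        }
      }
    }
    return level[t] >= 0;
  }

  // iterative blocking-flow DFS (avoids deep recursion on large grids)
  double dfs_blocking(int s, int t, std::vector<std::pair<int,double> > *rec) {
    double total = 0.0;
    std::vector<int> path; path.reserve(64);
    int u = s;
    while (true) {
      if (u == t) {
        double bottleneck = std::numeric_limits<double>::infinity();
        for (size_t i = 0; i < path.size(); ++i)
          bottleneck = std::min(bottleneck, cap[path[i]]);
        for (size_t i = 0; i < path.size(); ++i) {
          int e = path[i];
          cap[e] -= bottleneck;
          cap[e ^ 1] += bottleneck;
          if (rec) rec->push_back(std::make_pair(e, bottleneck));
        }
        total += bottleneck;
        // retreat to the first saturated arc on the path
        size_t cutpos = 0;
        while (cutpos < path.size() && cap[path[cutpos]] > FLOW_EPS) ++cutpos;
        path.resize(cutpos);
        u = path.empty() ? s : to[path.back()];
        continue;
      }
      int e;
      for (e = iter[u]; e != -1; e = nxt[e]) {
        if (cap[e] > FLOW_EPS && level[to[e]] == level[u] + 1) break;
      }
      iter[u] = e;
      if (e != -1) {              // advance
        path.push_back(e);
        u = to[e];
      } else {                    // dead end: prune and retreat
        level[u] = -1;
        if (path.empty()) break;
        path.pop_back();
        u = path.empty() ? s : to[path.back()];
      }
    }
    return total;
  }

  double maxflow(int s, int t, std::vector<std::pair<int,double> > *rec = 0) {
    double flow = 0.0;
    while (bfs_levels(s, t)) {
      iter = head;
      flow += dfs_blocking(s, t, rec);
    }
    return flow;
  }

  // labels: 0 = reachable from S in residual graph (source side)
  IntegerVector residual_labels() {
    std::vector<char> vis(n + 2, 0);
    std::queue<int> q;
    vis[S] = 1; q.push(S);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int e = head[u]; e != -1; e = nxt[e]) {
        int v = to[e];
        if (cap[e] > FLOW_EPS && !vis[v]) { vis[v] = 1; q.push(v); }
      }
    }
    IntegerVector lab(n);
    for (int i = 0; i < n; ++i) lab[i] = vis[i] ? 0 : 1;
    return lab;
  }

  // Max residual flow between a terminal and node v, with the BFS rooted at
  // v so the search stays local to v's residual pocket (terminal arcs make
  // the opposite terminal reachable within a few hops until the cut around
  // v saturates). Every push is recorded so the state can be rolled back.
  //
  // to_sink = true : max residual flow v ~> T (BFS forward from v)
  // to_sink = false: max residual flow S ~> v (BFS backward from v: arc
  //                  u -> w is traversed from w to u while cap[e] remains)
  std::vector<int> vis_stamp, par_arc;
  int stamp = 0;

  double residual_flow_at(int v, bool to_sink,
                          std::vector<std::pair<int,double> > &rec,
                          double cutoff) {
    double extra = 0.0;
    int target = to_sink ? T : S;
    if ((int)vis_stamp.size() != n + 2) {
      vis_stamp.assign(n + 2, 0);
      par_arc.assign(n + 2, -1);
    }
    while (extra < cutoff) {
      ++stamp;
      std::queue<int> q;
      vis_stamp[v] = stamp; q.push(v);
      bool found = false;
      while (!q.empty() && !found) {
        int u = q.front(); q.pop();
        for (int e = head[u]; e != -1; e = nxt[e]) {
          int w = to[e];
          // forward search uses arc e (u -> w); backward search uses the
          // partner arc e^1 (w -> u), whose residual is cap[e ^ 1]
          double c = to_sink ? cap[e] : cap[e ^ 1];
          if (c > FLOW_EPS && vis_stamp[w] != stamp) {
            vis_stamp[w] = stamp;
            par_arc[w] = to_sink ? e : (e ^ 1);
            if (w == target) { found = true; break; }
            q.push(w);
          }
        }
      }
      if (!found) break;
      // reconstruct the path between v and the terminal
      double bottleneck = std::numeric_limits<double>::infinity();
      for (int u = target; u != v; ) {
        int e = par_arc[u];
        bottleneck = std::min(bottleneck, cap[e]);
        u = to_sink ? to[e ^ 1] : to[e];
      }
      for (int u = target; u != v; ) {
        int e = par_arc[u];
        cap[e] -= bottleneck;
        cap[e ^ 1] += bottleneck;
        rec.push_back(std::make_pair(e, bottleneck));
        u = to_sink ? to[e ^ 1] : to[e];
      }
      extra += bottleneck;
    }
    return extra;
  }

  void rollback(std::vector<std::pair<int,double> > &rec) {
    for (size_t i = rec.size(); i-- > 0; ) {
      cap[rec[i].first] += rec[i].second;
      cap[rec[i].first ^ 1] -= rec[i].second;
    }
    rec.clear();
  }
};

static FlowGraph build_graph(int n, NumericVector cap_source,
                             NumericVector cap_sink, IntegerVector ei,
                             IntegerVector ej, NumericVector cap_ij,
                             NumericVector cap_ji) {
  FlowGraph g(n);
  for (int i = 0; i < n; ++i)
    g.add_arc_pair(g.S, i, cap_source[i], 0.0);   // arc pair (S->i, i->S)
  for (int i = 0; i < n; ++i)
    g.add_arc_pair(i, g.T, cap_sink[i], 0.0);
  for (int e = 0; e < ei.size(); ++e)
    g.add_arc_pair(ei[e] - 1, ej[e] - 1, cap_ij[e], cap_ji[e]);
  return g;
}

// [[Rcpp::export]]
List cpp_maxflow(int n, NumericVector cap_source, NumericVector cap_sink,
                 IntegerVector edge_i, IntegerVector edge_j,
                 NumericVector cap_ij, NumericVector cap_ji) {
  FlowGraph g = build_graph(n, cap_source, cap_sink, edge_i, edge_j,
                            cap_ij, cap_ji);
  double flow = g.maxflow(g.S, g.T);
  IntegerVector labels = g.residual_labels();
  return List::create(_["flow"] = flow, _["labels"] = labels);
}

// Min-marginal energies psi0/psi1 for the requested nodes (1-based).
// For a node on the source side (label 0), psi0 = F and
// psi1 = F + max residual flow S ~> v (forcing v to the sink adds an
// infinite arc v->T; all new augmenting paths are S ~> v -> T). Symmetric
// for sink-side nodes. Pushes are rolled back after each node so the
// constrained solves are independent and exactly reusable.
// [[Rcpp::export]]
List cpp_min_marginals(int n, NumericVector cap_source, NumericVector cap_sink,
                       IntegerVector edge_i, IntegerVector edge_j,
                       NumericVector cap_ij, NumericVector cap_ji,
                       IntegerVector nodes, double cutoff) {
  FlowGraph g = build_graph(n, cap_source, cap_sink, edge_i, edge_j,
                            cap_ij, cap_ji);
  double F = g.maxflow(g.S, g.T);
  IntegerVector labels = g.residual_labels();

  int m = nodes.size();
  NumericVector psi0(m), psi1(m);
  std::vector<std::pair<int,double> > rec;
  rec.reserve(1024);
  for (int idx = 0; idx < m; ++idx) {
    int v = nodes[idx] - 1;
    if (v < 0 || v >= n) stop("node index out of range");
    if (labels[v] == 0) {
      psi0[idx] = F;
      // forcing label 1 adds an infinite arc v -> T; extra flow = S ~> v
      double extra = g.residual_flow_at(v, false, rec, cutoff);
      psi1[idx] = F + extra;
      g.rollback(rec);
    } else {
      psi1[idx] = F;
      // forcing label 0 adds an infinite arc S -> v; extra flow = v ~> T
      double extra = g.residual_flow_at(v, true, rec, cutoff);
      psi0[idx] = F + extra;
      g.rollback(rec);
    }
  }
  return List::create(_["flow"] = F, _["labels"] = labels,
                      _["psi0"] = psi0, _["psi1"] = psi1);
}

// cubic B-spline kernel, unit knot spacing (partition of unity over shifts)
static inline double bspline3(double t) {
  double a = std::fabs(t);
  if (a < 1.0) return (4.0 - 6.0 * a * a + 3.0 * a * a * a) / 6.0;
  if (a < 2.0) { double b = 2.0 - a; return b * b * b / 6.0; }
  return 0.0;
}

// Spatially weighted joint histogram with Parzen intensity windows.
// rv/fv are intensities already mapped to continuous bin coordinates in
// [0, nbins-1]; w is the per-sample spatial weight. Out-of-range kernel
// taps are accumulated into the edge bins so total mass is sum(w).
// [[Rcpp::export]]
NumericMatrix cpp_parzen_hist(NumericVector rv, NumericVector fv,
                              NumericVector w, int nbins, bool cubic) {
  NumericMatrix H(nbins, nbins);
  int ns = rv.size();
  for (int s = 0; s < ns; ++s) {
    double x = rv[s], y = fv[s], ws = w[s];
    if (ws <= 0.0 || !R_finite(x) || !R_finite(y)) continue;
    if (!cubic) {
      int i = (int)std::lround(x), j = (int)std::lround(y);
      if (i < 0) i = 0;
      if (i >= nbins) i = nbins - 1;
      if (j < 0) j = 0;
      if (j >= nbins) j = nbins - 1;
      H(i, j) += ws;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y);
    for (int di = -1; di <= 2; ++di) {
      int i = i0 + di;
      double wi = bspline3(x - i);
      if (wi <= 0.0) continue;
      int ic = i < 0 ? 0 : (i >= nbins ? nbins - 1 : i);
      for (int dj = -1; dj <= 2; ++dj) {
        int j = j0 + dj;
        double wj = bspline3(y - j);
        if (wj <= 0.0) continue;
        int jc = j < 0 ? 0 : (j >= nbins ? nbins - 1 : j);
        H(ic, jc) += ws * wi * wj;
      }
    }
  }
  return H;
}
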