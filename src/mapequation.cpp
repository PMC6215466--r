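// Two-level map equation (Infomap-style) community detection for weighted
// undirected graphs.
//
// The description length of a random walk under a two-level codebook is
//   L(M) = plogp(sum_i q_i) - 2 * sum_i plogp(q_i)
//        - sum_a plogp(p_a) + sum_i plogp(q_i + m_i)
// with plogp(x) = x log2 x, p_a the stationary visit rate of node a
// (strength / 2W), q_i the exit probability of module i (crossing edge
// weight / 2W) and m_i the total visit rate inside module i.  L is
// minimised by seeded greedy node moving with Louvain-style aggregation
// and multiple restarts; everything is deterministic given the seed.

#include <Rcpp.h>
#include <vector>
#include <random>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double plogp(double x) {
  return (x > 0.0) ? x * std::log2(x) : 0.0;
}

struct Level {
  int n;
  std::vector<double> p;                    // visit mass per node
  std::vector<double> s;                    // external flow per node
  std::vector<std::vector<std::pair<int, double>>> adj;  // inter-node flows
};

struct State {
  std::vector<int> member;
  std::vector<double> q, m;
  double SQ, A, B;
  double codelength(double C) const {
    return plogp(SQ) - 2.0 * A + B - C;
  }
};

static State init_state(const Level& g) {
  State st;
  st.member.resize(g.n);
  st.q = g.s;
  st.m = g.p;
  st.SQ = 0;
  st.A = 0;
  st.B = 0;
  for (int i = 0; i < g.n; ++i) {
    st.member[i] = i;
    st.SQ += st.q[i];
    st.A += plogp(st.q[i]);
    st.B += plogp(st.q[i] + st.m[i]);
  }
  return st;
}

// One pass of greedy node moving; returns true if any node moved.
static bool move_nodes(const Level& g, State& st, std::mt19937& rng) {
  std::vector<int> order(g.n);
  for (int i = 0; i < g.n; ++i) order[i] = i;
  std::shuffle(order.begin(), order.end(), rng);
  std::vector<double> wmod(g.n, 0.0);
  bool any = false;
  for (int oi = 0; oi < g.n; ++oi) {
    int a = order[oi];
    int mi = st.member[a];
    std::vector<int> touched;
    for (auto& e : g.adj[a]) {
      int mb = st.member[e.first];
      if (wmod[mb] == 0.0) touched.push_back(mb);
      wmod[mb] += e.second;
    }
    double pa = g.p[a], sa = g.s[a];
    double w_ai = wmod[mi];
    // removal of a from its module
    double qi_new = st.q[mi] - sa + 2.0 * w_ai;
    double base_SQ = st.SQ - st.q[mi] + qi_new;
    double base_A = st.A - plogp(st.q[mi]) + plogp(qi_new);
    double base_B = st.B - plogp(st.q[mi] + st.m[mi]) +
                    plogp(qi_new + st.m[mi] - pa);
    double bestDelta = 0.0;
    int bestMod = mi;
    double cur = plogp(st.SQ) - 2.0 * st.A + st.B;
    std::sort(touched.begin(), touched.end());  // deterministic tie-break
    for (int mj : touched) {
      if (mj == mi) continue;
      double w_aj = wmod[mj];
      double qj_new = st.q[mj] + sa - 2.0 * w_aj;
      double SQ2 = base_SQ - st.q[mj] + qj_new;
      double A2 = base_A - plogp(st.q[mj]) + plogp(qj_new);
      double B2 = base_B - plogp(st.q[mj] + st.m[mj]) +
                  plogp(qj_new + st.m[mj] + pa);
      double L2 = plogp(SQ2) - 2.0 * A2 + B2;
      double delta = L2 - cur;
      if (delta < bestDelta - 1e-13) {
        bestDelta = delta;
        bestMod = mj;
      }
    }
    if (bestMod != mi) {
      double w_aj = wmod[bestMod];
      st.SQ += -st.q[mi] - st.q[bestMod];
      st.A -= plogp(st.q[mi]) + plogp(st.q[bestMod]);
      st.B -= plogp(st.q[mi] + st.m[mi]) + plogp(st.q[bestMod] + st.m[bestMod]);
      st.q[mi] += -sa + 2.0 * w_ai;
      st.q[bestMod] += sa - 2.0 * w_aj;
      st.m[mi] -= pa;
      st.m[bestMod] += pa;
      st.SQ += st.q[mi] + st.q[bestMod];
      st.A += plogp(st.q[mi]) + plogp(st.q[bestMod]);
      st.B += plogp(st.q[mi] + st.m[mi]) + plogp(st.q[bestMod] + st.m[bestMod]);
      st.member[a] = bestMod;
      any = true;
    }
    for (int mb : touched) wmod[mb] = 0.0;
  }
  return any;
}

static std::vector<int> compact(const std::vector<int>& member) {
  std::vector<int> map(member.size(), -1);
  std::vector<int> out(member.size());
  int next = 0;
  for (size_t i = 0; i < member.size(); ++i) {
    if (map[member[i]] < 0) map[member[i]] = next++;
    out[i] = map[member[i]];
  }
  return out;
}

static Level aggregate(const Level& g, const std::vector<int>& member, int k) {
  Level s;
  s.n = k;
  s.p.assign(k, 0.0);
  s.s.assign(k, 0.0);
  s.adj.assign(k, {});
  for (int i = 0; i < g.n; ++i) s.p[member[i]] += g.p[i];
  std::vector<double> acc(k, 0.0);
  for (int mi = 0; mi < k; ++mi) {
    std::vector<int> touched;
    for (int i = 0; i < g.n; ++i) {
      if (member[i] != mi) continue;
      for (auto& e : g.adj[i]) {
        int mj = member[e.first];
        if (mj == mi) continue;
        if (acc[mj] == 0.0) touched.push_back(mj);
        acc[mj] += e.second;
      }
    }
    std::sort(touched.begin(), touched.end());
    for (int mj : touched) {
      s.adj[mi].push_back({mj, acc[mj]});
      s.s[mi] += acc[mj];
      acc[mj] = 0.0;
    }
  }
  return s;
}

static double optimize(const Level& g, double C, std::mt19937& rng,
                       std::vector<int>& member_out) {
  State st = init_state(g);
  while (move_nodes(g, st, rng)) {}
  std::vector<int> member = compact(st.member);
  int k = *std::max_element(member.begin(), member.end()) + 1;
  double L = st.codelength(C);
  // Louvain-style aggregation: move whole modules, expand, repeat.
  while (k < g.n) {
    Level sg = aggregate(g, member, k);
    State sst = init_state(sg);
    bool any = false;
    while (move_nodes(sg, sst, rng)) any = true;
    if (!any) break;
    std::vector<int> smember = compact(sst.member);
    for (size_t i = 0; i < member.size(); ++i) member[i] = smember[member[i]];
    member = compact(member);
    int k2 = *std::max_element(member.begin(), member.end()) + 1;
    double L2 = sst.codelength(C);
    if (L2 > L - 1e-13 || k2 == k) break;
    L = L2;
    k = k2;
    // fine-tune at node level from the aggregated solution
    State ft = init_state(g);
    // rebuild module sums for the expanded membership
    ft.member = member;
    ft.q.assign(k, 0.0);
    ft.m.assign(k, 0.0);
    for (int i = 0; i < g.n; ++i) {
      ft.m[member[i]] += g.p[i];
      for (auto& e : g.adj[i])
        if (member[e.first] != member[i]) ft.q[member[i]] += e.second;
    }
    ft.SQ = 0; ft.A = 0; ft.B = 0;
    for (int j = 0; j < k; ++j) {
      ft.SQ += ft.q[j];
      ft.A += plogp(ft.q[j]);
      ft.B += plogp(ft.q[j] + ft.m[j]);
    }
    // allow empty trailing modules by padding state vectors to g.n
    ft.q.resize(g.n, 0.0);
    ft.m.resize(g.n, 0.0);
    bool moved = false;
    while (move_nodes(g, ft, rng)) moved = true;
    if (moved && ft.codelength(C) < L - 1e-13) {
      member = compact(ft.member);
      k = *std::max_element(member.begin(), member.end()) + 1;
      L = ft.codelength(C);
    }
  }
  member_out = member;
  return L;
}

// [[Rcpp::export(name = ".map_equation_cpp")]]
List map_equation_cpp(int n, IntegerVector ei, IntegerVector ej,
                      NumericVector w, int seed, int n_restarts) {
  Level g;
  g.n = n;
  g.p.assign(n, 0.0);
  g.s.assign(n, 0.0);
  g.adj.assign(n, {});
  double W = 0.0;
  for (int e = 0; e < ei.size(); ++e) W += w[e];
  if (W <= 0.0 || ei.size() == 0) {
    IntegerVector mem(n);
    for (int i = 0; i < n; ++i) mem[i] = i + 1;
    return List::create(_["membership"] = mem, _["codelength"] = 0.0);
  }
  for (int e = 0; e < ei.size(); ++e) {
    double v = w[e] / (2.0 * W);
    int a = ei[e], b = ej[e];
    g.adj[a].push_back({b, v});
    g.adj[b].push_back({a, v});
    g.p[a] += v;
    g.p[b] += v;
    g.s[a] += v;
    g.s[b] += v;
  }
  double C = 0.0;
  for (int i = 0; i < n; ++i) C += plogp(g.p[i]);
  double bestL = R_PosInf;
  std::vector<int> best;
  for (int r = 0; r < std::max(1, n_restarts); ++r) {
    std::mt19937 rng((unsigned)(seed * 1000003u + 97u * r + 11u));
    std::vector<int> member;
    double L = optimize(g, C, rng, member);
    if (L < bestL - 1e-13) {
      bestL = L;
      best = member;
    }
  }
  std::vector<int> mem = compact(best);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = mem[i] + 1;
  return List::create(_["membership"] = out, _["codelength"] = bestL);
}
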