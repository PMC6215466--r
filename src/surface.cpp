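// Surface watershed primitives.
//
// Vertex-based Beucher/Meyer flooding on a triangle-mesh adjacency graph:
// basins grow from seed minima in ascending order of the scalar field; a
// vertex whose already-flooded neighbours belong to >= 2 distinct basins
// becomes a ridge (label 0, boundary image 1).  Ties are broken by
// (value, vertex index) so results are fully deterministic.

#include <Rcpp.h>
#include <queue>
#include <deque>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct QItem {
  double value;
  int vertex;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.value != b.value) return a.value > b.value;  // min-heap on value
    return a.vertex > b.vertex;                        // then lowest index
  }
};

// Adjacency passed as CSR: offsets (V+1), neighbours (2E), both 0-based.
static void flood(const IntegerVector& off, const IntegerVector& nbr,
                  const NumericVector& values, const LogicalVector& medial,
                  const std::vector<int>& seeds, double ceiling,
                  std::vector<int>& label, std::vector<bool>& ridge) {
  const int V = values.size();
  label.assign(V, 0);
  ridge.assign(V, false);
  std::vector<char> state(V, 0);  // 0 unseen, 1 queued, 2 done
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  for (size_t k = 0; k < seeds.size(); ++k) {
    int s = seeds[k];
    label[s] = (int)k + 1;
    pq.push({values[s], s});
    state[s] = 1;
  }
  while (!pq.empty()) {
    QItem it = pq.top();
    pq.pop();
    int v = it.vertex;
    if (state[v] == 2) continue;
    state[v] = 2;
    if (label[v] == 0) {
      int lab = 0;
      bool mixed = false;
      for (int j = off[v]; j < off[v + 1]; ++j) {
        int u = nbr[j];
        if (state[u] == 2 && label[u] > 0) {
          if (lab == 0) lab = label[u];
          else if (lab != label[u]) { mixed = true; break; }
        }
      }
      if (mixed || lab == 0) {
        // adjacent to >= 2 basins, or reachable only through ridge
        // vertices (degenerate plateau): boundary.
        ridge[v] = true;
        continue;  // ridges do not propagate labels
      }
      label[v] = lab;
    }
    for (int j = off[v]; j < off[v + 1]; ++j) {
      int u = nbr[j];
      if (state[u] != 0 || medial[u]) continue;
      double val = values[u];
      if (!R_finite(val) || val > ceiling) continue;
      state[u] = 1;
      pq.push({val, u});
    }
  }
}

// [[Rcpp::export(name = ".watershed_cpp")]]
List watershed_cpp(IntegerVector off, IntegerVector nbr, NumericVector values,
                   LogicalVector medial, IntegerVector seeds0, double ceiling) {
  std::vector<int> seeds(seeds0.begin(), seeds0.end());
  std::vector<int> label;
  std::vector<bool> ridge;
  flood(off, nbr, values, medial, seeds, ceiling, label, ridge);
  const int V = values.size();
  IntegerVector lab(V);
  LogicalVector rid(V);
  for (int v = 0; v < V; ++v) {
    lab[v] = label[v];
    rid[v] = ridge[v];
  }
  return List::create(_["labels"] = lab, _["ridge"] = rid);
}

// Regional minima: connected equal-valued plateaus with no strictly lower
// valid neighbour anywhere on the plateau; each surviving plateau is
// represented by its lowest vertex index.
static std::vector<int> minima(const IntegerVector& off, const IntegerVector& nbr,
                               const NumericVector& values,
                               const LogicalVector& medial) {
  const int V = values.size();
  std::vector<int> rep;
  std::vector<bool> seen(V, false);
  for (int v = 0; v < V; ++v) {
    if (seen[v] || medial[v] || !R_finite(values[v])) continue;
    // flood the equal-valued plateau containing v
    int best = v;
    bool has_lower = false;
    std::vector<int> stack{v};
    seen[v] = true;
    while (!stack.empty()) {
      int w = stack.back();
      stack.pop_back();
      if (w < best) best = w;
      for (int j = off[w]; j < off[w + 1]; ++j) {
        int u = nbr[j];
        if (medial[u] || !R_finite(values[u])) continue;
        if (values[u] < values[v]) has_lower = true;
        else if (values[u] == values[v] && !seen[u]) {
          seen[u] = true;
          stack.push_back(u);
        }
      }
    }
    if (!has_lower) rep.push_back(best);
  }
  std::sort(rep.begin(), rep.end());
  return rep;
}

// h-minima transform: morphological reconstruction by erosion of f + h
// over f.  Basins shallower than h (relative to their lowest saddle) are
// filled, so the subsequent minima/watershed ignore them.
static std::vector<double> hmin_transform(const IntegerVector& off,
                                          const IntegerVector& nbr,
                                          const NumericVector& values,
                                          const LogicalVector& medial,
                                          double h) {
  const int V = values.size();
  std::vector<double> r(V);
  std::deque<int> fifo;
  std::vector<bool> queued(V, false);
  for (int v = 0; v < V; ++v) {
    if (medial[v] || !R_finite(values[v])) {
      r[v] = values[v];
      continue;
    }
    r[v] = values[v] + h;
    fifo.push_back(v);
    queued[v] = true;
  }
  while (!fifo.empty()) {
    int v = fifo.front();
    fifo.pop_front();
    queued[v] = false;
    if (medial[v] || !R_finite(values[v])) continue;
    double m = r[v];
    for (int j = off[v]; j < off[v + 1]; ++j) {
      int u = nbr[j];
      if (medial[u] || !R_finite(values[u])) continue;
      if (r[u] < m) m = r[u];
    }
    double val = std::max((double)values[v], m);
    if (val < r[v] - 1e-15) {
      r[v] = val;
      for (int j = off[v]; j < off[v + 1]; ++j) {
        int u = nbr[j];
        if (!queued[u] && !medial[u] && R_finite(values[u])) {
          queued[u] = true;
          fifo.push_back(u);
        }
      }
    }
  }
  return r;
}

// [[Rcpp::export(name = ".hminima_cpp")]]
NumericVector hminima_cpp(IntegerVector off, IntegerVector nbr,
                          NumericVector values, LogicalVector medial,
                          double h) {
  std::vector<double> r = hmin_transform(off, nbr, values, medial, h);
  return NumericVector(r.begin(), r.end());
}

// [[Rcpp::export(name = ".local_minima_cpp")]]
IntegerVector local_minima_cpp(IntegerVector off, IntegerVector nbr,
                               NumericVector values, LogicalVector medial) {
  std::vector<int> rep = minima(off, nbr, values, medial);
  return wrap(rep);
}

// Per-seed-column boundary accumulation: for each column of the mean
// gradient matrix, optionally apply the h-minima transform (h =
// min_depth_frac of the column's 5-95 percentile spread), then run
// minima-seeded full flooding and add the binary ridge image; returns
// the per-vertex ridge count and the number of columns processed.
// [[Rcpp::export(name = ".boundary_accumulate_cpp")]]
List boundary_accumulate_cpp(IntegerVector off, IntegerVector nbr,
                             NumericMatrix grad, LogicalVector medial,
                             IntegerVector cols0, double min_depth_frac) {
  const int V = grad.nrow();
  std::vector<double> count(V, 0.0);
  int used = 0;
  std::vector<int> label;
  std::vector<bool> ridge;
  for (int ci = 0; ci < cols0.size(); ++ci) {
    int c = cols0[ci];
    NumericVector col = grad(_, c);
    if (min_depth_frac > 0) {
      std::vector<double> vv;
      vv.reserve(V);
      for (int v = 0; v < V; ++v)
        if (!medial[v] && R_finite(col[v])) vv.push_back(col[v]);
      if (vv.size() > 10) {
        size_t i5 = (size_t)(0.05 * (vv.size() - 1));
        size_t i95 = (size_t)(0.95 * (vv.size() - 1));
        std::nth_element(vv.begin(), vv.begin() + i5, vv.end());
        double p5 = vv[i5];
        std::nth_element(vv.begin(), vv.begin() + i95, vv.end());
        double p95 = vv[i95];
        double h = min_depth_frac * (p95 - p5);
        if (h > 0) {
          std::vector<double> r = hmin_transform(off, nbr, col, medial, h);
          for (int v = 0; v < V; ++v) col[v] = r[v];
        }
      }
    }
    std::vector<int> seeds = minima(off, nbr, col, medial);
    if (seeds.empty()) continue;
    flood(off, nbr, col, medial, seeds, R_PosInf, label, ridge);
    for (int v = 0; v < V; ++v)
      if (ridge[v]) count[v] += 1.0;
    ++used;
    if (ci % 256 == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector cnt(count.begin(), count.end());
  return List::create(_["count"] = cnt, _["n_cols"] = used);
}
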