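// Watershed flooding on a triangle-mesh vertex graph.
//
// Seeding: candidate vertices have a value <= every defined vertex in their
// 3-ring neighborhood (BFS within the defined subgraph). Candidates are
// grouped into plateau components (edge-connected, equal value); each
// component contributes one seed, its lowest vertex index, so flat regions
// seed deterministically and a constant map yields one region per
// component.
//
// Flooding: a min-heap keyed by (value, vertex index) grows regions in
// globally ascending order. At pop time a vertex adjacent to exactly one
// labeled region joins it; a vertex adjacent to >= 2 distinct regions is an
// ambiguous location and becomes boundary (label 0, boundary flag set).
// Vertices never reached (possible only behind closed boundary ridges) are
// marked boundary for determinism.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct QItem {
  double value;
  int vertex;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.value != b.value) return a.value > b.value;
    return a.vertex > b.vertex;
  }
};

// one watershed flood; labels out: 0 = boundary/undefined, 1..n regions
void flood(const std::vector<double>& val, const std::vector<bool>& defined,
           const IntegerVector& ptr, const IntegerVector& idx,
           std::vector<int>& labels, std::vector<bool>& boundary) {
  const int nv = (int)val.size();
  labels.assign(nv, 0);
  boundary.assign(nv, false);

  // 3-ring minima candidates (BFS depth 3 in the defined subgraph)
  std::vector<bool> cand(nv, false);
  std::vector<int> depth(nv, -1);
  std::vector<int> touched;
  for (int v = 0; v < nv; ++v) {
    if (!defined[v]) continue;
    bool is_min = true;
    touched.clear();
    depth[v] = 0;
    touched.push_back(v);
    std::queue<int> bfs;
    bfs.push(v);
    while (!bfs.empty() && is_min) {
      int u = bfs.front(); bfs.pop();
      if (depth[u] == 3) continue;
      for (int k = ptr[u]; k < ptr[u + 1]; ++k) {
        int w = idx[k];
        if (!defined[w] || depth[w] >= 0) continue;
        depth[w] = depth[u] + 1;
        touched.push_back(w);
        if (val[w] < val[v]) { is_min = false; break; }
        bfs.push(w);
      }
    }
    for (int u : touched) depth[u] = -1;
    cand[v] = is_min;
  }

  // plateau components among candidates: one seed per component (min index)
  int next_label = 0;
  std::vector<bool> visited(nv, false);
  for (int v = 0; v < nv; ++v) {
    if (!cand[v] || visited[v]) continue;
    // BFS over equal-valued candidate neighbors
    std::vector<int> comp;
    std::queue<int> bfs;
    bfs.push(v);
    visited[v] = true;
    while (!bfs.empty()) {
      int u = bfs.front(); bfs.pop();
      comp.push_back(u);
      for (int k = ptr[u]; k < ptr[u + 1]; ++k) {
        int w = idx[k];
        if (!visited[w] && cand[w] && val[w] == val[u]) {
          visited[w] = true;
          bfs.push(w);
        }
      }
    }
    int seed = *std::min_element(comp.begin(), comp.end());
    labels[seed] = ++next_label;
  }

  // priority flood
  std::priority_queue<QItem, std::vector<QItem>, QCmp> heap;
  std::vector<bool> queued(nv, false);
  for (int v = 0; v < nv; ++v) {
    if (labels[v] == 0) continue;
    for (int k = ptr[v]; k < ptr[v + 1]; ++k) {
      int w = idx[k];
      if (defined[w] && labels[w] == 0 && !queued[w]) {
        queued[w] = true;
        heap.push({val[w], w});
      }
    }
  }
  while (!heap.empty()) {
    int v = heap.top().vertex;
    heap.pop();
    if (labels[v] != 0 || boundary[v]) continue;
    int lab = 0;
    bool ambiguous = false;
    for (int k = ptr[v]; k < ptr[v + 1]; ++k) {
      int w = idx[k];
      if (labels[w] > 0) {
        if (lab == 0) lab = labels[w];
        else if (labels[w] != lab) { ambiguous = true; break; }
      }
    }
    if (ambiguous) {
      boundary[v] = true;
    } else if (lab > 0) {
      labels[v] = lab;
      for (int k = ptr[v]; k < ptr[v + 1]; ++k) {
        int w = idx[k];
        if (defined[w] && labels[w] == 0 && !boundary[w]) {
          // re-push is fine; stale pops are skipped above
          heap.push({val[w], w});
        }
      }
    }
    // lab == 0: all labeled neighbors became boundary meanwhile; vertex
    // will be re-pushed if a neighbor is labeled later, else unreached
  }
  for (int v = 0; v < nv; ++v)
    if (defined[v] && labels[v] == 0 && !boundary[v])
      boundary[v] = true;
}

} // namespace

// [[Rcpp::export(name = ".ws_flood")]]
List ws_flood(NumericVector values, LogicalVector defined,
              IntegerVector adj_ptr, IntegerVector adj_idx) {
  const int nv = values.size();
  std::vector<double> val(nv);
  std::vector<bool> def(nv);
  for (int v = 0; v < nv; ++v) {
    bool d = defined[v] && !NumericVector::is_na(values[v]);
    def[v] = d;
    val[v] = d ? values[v] : 0.0;
  }
  std::vector<int> labels;
  std::vector<bool> boundary;
  flood(val, def, adj_ptr, adj_idx, labels, boundary);
  IntegerVector lab(nv);
  LogicalVector bnd(nv);
  for (int v = 0; v < nv; ++v) {
    lab[v] = labels[v];
    bnd[v] = boundary[v];
  }
  return List::create(_["labels"] = lab, _["boundary"] = bnd);
}

// [[Rcpp::export(name = ".ws_boundary_rows")]]
List ws_boundary_rows(NumericMatrix grad_rows, LogicalVector defined,
                      IntegerVector adj_ptr, IntegerVector adj_idx) {
  const int nrow = grad_rows.nrow();
  const int nv = grad_rows.ncol();
  std::vector<double> counts(nv, 0.0);
  int n_valid = 0;
  std::vector<double> val(nv);
  std::vector<bool> def(nv);
  std::vector<int> labels;
  std::vector<bool> boundary;
  for (int r = 0; r < nrow; ++r) {
    bool any_def = false;
    for (int v = 0; v < nv; ++v) {
      bool d = defined[v] && !NumericVector::is_na(grad_rows(r, v));
      def[v] = d;
      val[v] = d ? grad_rows(r, v) : 0.0;
      any_def = any_def || d;
    }
    if (!any_def) continue;
    flood(val, def, adj_ptr, adj_idx, labels, boundary);
    ++n_valid;
    for (int v = 0; v < nv; ++v)
      if (boundary[v]) counts[v] += 1.0;
  }
  NumericVector out(nv);
  for (int v = 0; v < nv; ++v) out[v] = counts[v];
  return List::create(_["counts"] = out, _["n_valid"] = n_valid);
}
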