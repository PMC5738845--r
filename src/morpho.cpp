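#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// 3D morphology on scalar grids: seeded watershed (priority flood,
// 6-connectivity, FIFO tie-break for determinism), greyscale reconstruction
// by dilation (hybrid raster + queue algorithm), regional-minima labelling,
// and binary connected components.

struct QNode {
  double value;
  uint64_t order;
  R_xlen_t idx;
};
struct QCmp {
  bool operator()(const QNode &a, const QNode &b) const {
    if (a.value != b.value) return a.value > b.value;   // lowest value first
    return a.order > b.order;                           // FIFO among equals
  }
};

static inline void neighbours6(R_xlen_t id, int n1, int n2, int n3,
                               R_xlen_t *nb, int &cnt) {
  int i = (int)(id % n1);
  R_xlen_t r = id / n1;
  int j = (int)(r % n2);
  int k = (int)(r / n2);
  cnt = 0;
  if (i > 0)      nb[cnt++] = id - 1;
  if (i < n1 - 1) nb[cnt++] = id + 1;
  if (j > 0)      nb[cnt++] = id - n1;
  if (j < n2 - 1) nb[cnt++] = id + n1;
  if (k > 0)      nb[cnt++] = id - (R_xlen_t)n1 * n2;
  if (k < n3 - 1) nb[cnt++] = id + (R_xlen_t)n1 * n2;
}

// [[Rcpp::export]]
IntegerVector watershed_cpp(NumericVector img, IntegerVector seeds,
                            IntegerVector dims, LogicalVector mask) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  const bool use_mask = mask.size() == n;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;
  std::priority_queue<QNode, std::vector<QNode>, QCmp> pq;
  uint64_t order = 0;
  R_xlen_t nb[6]; int cnt;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (seeds[i] > 0 && (!use_mask || mask[i])) {
      lab[i] = seeds[i];
      pq.push({img[i], order++, i});
    }
  }
  while (!pq.empty()) {
    QNode t = pq.top(); pq.pop();
    neighbours6(t.idx, n1, n2, n3, nb, cnt);
    for (int q = 0; q < cnt; ++q) {
      R_xlen_t m = nb[q];
      if (lab[m] == 0 && (!use_mask || mask[m])) {
        lab[m] = lab[t.idx];
        pq.push({img[m], order++, m});
      }
    }
  }
  return lab;
}

// greyscale reconstruction by dilation of marker under mask (marker <= mask
// required); hybrid algorithm: forward/backward raster sweeps then FIFO queue.
// [[Rcpp::export]]
NumericVector reconstruct_dilation_cpp(NumericVector marker, NumericVector mask,
                                       IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> J(marker.begin(), marker.end());
  const double *I = mask.begin();

  // forward sweep: neighbours already visited in raster order
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        R_xlen_t id = i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
        double m = J[id];
        if (i > 0) m = std::max(m, J[id - 1]);
        if (j > 0) m = std::max(m, J[id - n1]);
        if (k > 0) m = std::max(m, J[id - (R_xlen_t)n1 * n2]);
        J[id] = std::min(m, I[id]);
      }
  // backward sweep + queue seeding
  std::queue<R_xlen_t> fifo;
  for (int k = n3 - 1; k >= 0; --k)
    for (int j = n2 - 1; j >= 0; --j)
      for (int i = n1 - 1; i >= 0; --i) {
        R_xlen_t id = i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
        double m = J[id];
        if (i < n1 - 1) m = std::max(m, J[id + 1]);
        if (j < n2 - 1) m = std::max(m, J[id + n1]);
        if (k < n3 - 1) m = std::max(m, J[id + (R_xlen_t)n1 * n2]);
        J[id] = std::min(m, I[id]);
        // enqueue if a later-scanned neighbour could still be raised
        bool push = false;
        if (i < n1 - 1 && J[id + 1] < J[id] && J[id + 1] < I[id + 1]) push = true;
        if (!push && j < n2 - 1 && J[id + n1] < J[id] && J[id + n1] < I[id + n1]) push = true;
        if (!push && k < n3 - 1) {
          R_xlen_t q = id + (R_xlen_t)n1 * n2;
          if (J[q] < J[id] && J[q] < I[q]) push = true;
        }
        if (push) fifo.push(id);
      }
  R_xlen_t nb[6]; int cnt;
  while (!fifo.empty()) {
    R_xlen_t id = fifo.front(); fifo.pop();
    neighbours6(id, n1, n2, n3, nb, cnt);
    for (int q = 0; q < cnt; ++q) {
      R_xlen_t m = nb[q];
      if (J[m] < J[id] && I[m] != J[m]) {
        J[m] = std::min(J[id], I[m]);
        fifo.push(m);
      }
    }
  }
  NumericVector out(J.begin(), J.end());
  out.attr("dim") = dims;
  return out;
}

// label connected components (6-connectivity) of plateaus that are regional
// minima of img within mask; labels assigned in order of the smallest linear
// index of each component (deterministic).
// [[Rcpp::export]]
IntegerVector regional_minima_cpp(NumericVector img, IntegerVector dims,
                                  LogicalVector mask) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  const bool use_mask = mask.size() == n;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;
  std::vector<char> visited(n, 0);
  std::vector<R_xlen_t> comp;
  R_xlen_t nb[6]; int cnt;
  int next_label = 0;

  for (R_xlen_t s = 0; s < n; ++s) {
    if (visited[s] || (use_mask && !mask[s])) continue;
    // BFS over the plateau of equal value
    double v = img[s];
    bool is_min = true;
    comp.clear();
    std::queue<R_xlen_t> fifo;
    fifo.push(s);
    visited[s] = 1;
    while (!fifo.empty()) {
      R_xlen_t id = fifo.front(); fifo.pop();
      comp.push_back(id);
      neighbours6(id, n1, n2, n3, nb, cnt);
      for (int q = 0; q < cnt; ++q) {
        R_xlen_t m = nb[q];
        if (use_mask && !mask[m]) continue;
        if (img[m] == v) {
          if (!visited[m]) { visited[m] = 1; fifo.push(m); }
        } else if (img[m] < v) {
          is_min = false;
        }
      }
    }
    if (is_min) {
      ++next_label;
      for (size_t q = 0; q < comp.size(); ++q) lab[comp[q]] = next_label;
    }
  }
  return lab;
}

// binary connected components, 6-connectivity, labels in order of smallest
// linear index.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;
  R_xlen_t nb[6]; int cnt;
  int next_label = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next_label;
    std::queue<R_xlen_t> fifo;
    fifo.push(s);
    lab[s] = next_label;
    while (!fifo.empty()) {
      R_xlen_t id = fifo.front(); fifo.pop();
      neighbours6(id, n1, n2, n3, nb, cnt);
      for (int q = 0; q < cnt; ++q) {
        R_xlen_t m = nb[q];
        if (mask[m] && lab[m] == 0) { lab[m] = next_label; fifo.push(m); }
      }
    }
  }
  return lab;
}
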