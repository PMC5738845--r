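#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Exact Euclidean distance transform with nearest-site propagation
// (separable lower-envelope-of-parabolas algorithm, per axis, anisotropic
// spacing supported).  Returns squared distances and the 1-based linear
// index of (a) nearest site for every voxel.

static const double INF = std::numeric_limits<double>::infinity();

// 1D pass along one axis: d (squared distances), f (site indices), updated in place.
static void edt_1d(std::vector<double> &d, std::vector<int> &f,
                   int n, double w2,
                   std::vector<double> &dbuf, std::vector<int> &fbuf,
                   std::vector<int> &v, std::vector<double> &z) {
  int kq = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (d[q] == INF) continue;
    if (d[v[kq]] == INF) { v[kq] = q; continue; }
    double s;
    while (true) {
      int p = v[kq];
      s = ((d[q] + w2 * q * q) - (d[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[kq]) { --kq; }
      else break;
    }
    ++kq;
    v[kq] = q;
    z[kq] = s;
    z[kq + 1] = INF;
  }
  if (d[v[0]] == INF) return; // whole line empty of sites
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    int p = v[kk];
    dbuf[q] = d[p] + w2 * (q - p) * (double)(q - p);
    fbuf[q] = f[p];
  }
  for (int q = 0; q < n; ++q) { d[q] = dbuf[q]; f[q] = fbuf[q]; }
}

// [[Rcpp::export]]
List edt_cpp(LogicalVector sites, IntegerVector dims, NumericVector spacing) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> d(n);
  std::vector<int> f(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (sites[i]) { d[i] = 0.0; f[i] = (int)(i + 1); }
    else { d[i] = INF; f[i] = 0; }
  }
  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> line_d(nmax), dbuf(nmax), z(nmax + 1);
  std::vector<int> line_f(nmax), fbuf(nmax), v(nmax);

  // axis 1
  {
    double w2 = spacing[0] * spacing[0];
    for (int k = 0; k < n3; ++k)
      for (int j = 0; j < n2; ++j) {
        R_xlen_t base = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
        for (int i = 0; i < n1; ++i) { line_d[i] = d[base + i]; line_f[i] = f[base + i]; }
        edt_1d(line_d, line_f, n1, w2, dbuf, fbuf, v, z);
        for (int i = 0; i < n1; ++i) { d[base + i] = line_d[i]; f[base + i] = line_f[i]; }
      }
  }
  // axis 2
  {
    double w2 = spacing[1] * spacing[1];
    for (int k = 0; k < n3; ++k)
      for (int i = 0; i < n1; ++i) {
        for (int j = 0; j < n2; ++j) {
          R_xlen_t id = i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
          line_d[j] = d[id]; line_f[j] = f[id];
        }
        edt_1d(line_d, line_f, n2, w2, dbuf, fbuf, v, z);
        for (int j = 0; j < n2; ++j) {
          R_xlen_t id = i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
          d[id] = line_d[j]; f[id] = line_f[j];
        }
      }
  }
  // axis 3
  {
    double w2 = spacing[2] * spacing[2];
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        for (int k = 0; k < n3; ++k) {
          R_xlen_t id = i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
          line_d[k] = d[id]; line_f[k] = f[id];
        }
        edt_1d(line_d, line_f, n3, w2, dbuf, fbuf, v, z);
        for (int k = 0; k < n3; ++k) {
          R_xlen_t id = i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
          d[id] = line_d[k]; f[id] = line_f[k];
        }
      }
  }

  NumericVector dist2(d.begin(), d.end());
  IntegerVector idx(f.begin(), f.end());
  dist2.attr("dim") = dims;
  idx.attr("dim") = dims;
  return List::create(_["dist2"] = dist2, _["index"] = idx);
}
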