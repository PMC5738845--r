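#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Per-voxel eigenvalues of the symmetric 3x3 Hessian, by cyclic Jacobi
// rotations (robust for degenerate spectra), sorted descending.

static void jacobi3(double a[3][3], double w[3]) {
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off = std::fabs(a[0][1]) + std::fabs(a[0][2]) + std::fabs(a[1][2]);
    if (off == 0.0) break;
    for (int p = 0; p < 2; ++p)
      for (int q = p + 1; q < 3; ++q) {
        if (std::fabs(a[p][q]) < 1e-300) continue;
        double theta = (a[q][q] - a[p][p]) / (2.0 * a[p][q]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0);
        double s = t * c;
        double app = a[p][p], aqq = a[q][q], apq = a[p][q];
        a[p][p] = c * c * app - 2.0 * s * c * apq + s * s * aqq;
        a[q][q] = s * s * app + 2.0 * s * c * apq + c * c * aqq;
        a[p][q] = 0.0; a[q][p] = 0.0;
        int r = 3 - p - q;
        double apr = a[p][r], aqr = a[q][r];
        a[p][r] = c * apr - s * aqr; a[r][p] = a[p][r];
        a[q][r] = s * apr + c * aqr; a[r][q] = a[q][r];
      }
  }
  w[0] = a[0][0]; w[1] = a[1][1]; w[2] = a[2][2];
  // sort descending
  if (w[0] < w[1]) std::swap(w[0], w[1]);
  if (w[1] < w[2]) std::swap(w[1], w[2]);
  if (w[0] < w[1]) std::swap(w[0], w[1]);
}

// [[Rcpp::export]]
List hessian_eigenvalues_cpp(NumericVector hxx, NumericVector hyy, NumericVector hzz,
                             NumericVector hxy, NumericVector hxz, NumericVector hyz) {
  R_xlen_t n = hxx.size();
  NumericVector l1(n), l2(n), l3(n);
  double a[3][3], w[3];
  for (R_xlen_t i = 0; i < n; ++i) {
    a[0][0] = hxx[i]; a[1][1] = hyy[i]; a[2][2] = hzz[i];
    a[0][1] = a[1][0] = hxy[i];
    a[0][2] = a[2][0] = hxz[i];
    a[1][2] = a[2][1] = hyz[i];
    jacobi3(a, w);
    l1[i] = w[0]; l2[i] = w[1]; l3[i] = w[2];
  }
  SEXP d = hxx.attr("dim");
  if (d != R_NilValue) { l1.attr("dim") = d; l2.attr("dim") = d; l3.attr("dim") = d; }
  return List::create(_["l1"] = l1, _["l2"] = l2, _["l3"] = l3);
}
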