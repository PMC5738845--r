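#include <Rcpp.h>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Optimal (maximum total overlap) injective matching between the rows and
// columns of a non-negative overlap matrix, by dynamic programming over
// column subsets of the smaller side.  Exact up to min(nrow, ncol) <= 24.
// Returns the column matched to each row (0 = unmatched).

// [[Rcpp::export]]
List best_assignment_cpp(NumericMatrix overlap) {
  int nr = overlap.nrow(), nc = overlap.ncol();
  bool transposed = false;
  NumericMatrix O = overlap;
  if (nc > nr) {
    // transpose so that columns are the smaller side
    NumericMatrix T(nc, nr);
    for (int i = 0; i < nr; ++i)
      for (int j = 0; j < nc; ++j) T(j, i) = O(i, j);
    O = T; std::swap(nr, nc); transposed = true;
  }
  if (nc > 24) stop("best_assignment_cpp: too many labels for exact matching");

  const uint32_t M = 1u << nc;
  std::vector<double> dp(M, 0.0), dp_new(M);
  // choice[r][s]: column chosen for row r given incoming subset s (-1 = skip)
  std::vector<std::vector<int8_t> > choice(nr, std::vector<int8_t>(M, -1));

  for (int r = 0; r < nr; ++r) {
    for (uint32_t s = 0; s < M; ++s) dp_new[s] = -1.0;
    for (uint32_t s = 0; s < M; ++s) {
      if (dp[s] < 0) continue;
      // skip this row
      if (dp[s] > dp_new[s]) { dp_new[s] = dp[s]; choice[r][s] = -1; }
      for (int c = 0; c < nc; ++c) {
        if (s & (1u << c)) continue;
        uint32_t s2 = s | (1u << c);
        double val = dp[s] + O(r, c);
        if (val > dp_new[s2]) { dp_new[s2] = val; choice[r][s2] = (int8_t)c; }
      }
    }
    dp.swap(dp_new);
  }
  // best final subset
  uint32_t best_s = 0; double best = -1.0;
  for (uint32_t s = 0; s < M; ++s)
    if (dp[s] > best) { best = dp[s]; best_s = s; }
  // backtrack
  IntegerVector row_match(nr, 0);
  uint32_t s = best_s;
  for (int r = nr - 1; r >= 0; --r) {
    int c = choice[r][s];
    if (c >= 0) { row_match[r] = c + 1; s &= ~(1u << c); }
  }
  if (!transposed)
    return List::create(_["total"] = best, _["row_match"] = row_match,
                        _["transposed"] = false);
  // row_match currently maps columns of the original matrix to rows
  return List::create(_["total"] = best, _["row_match"] = row_match,
                      _["transposed"] = true);
}
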