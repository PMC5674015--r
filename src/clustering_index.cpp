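#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exact fixed-radius neighbour counts by uniform grid bucketing.
// Cell edge equals the search radius tau, so every neighbour of a point
// lies in the point's own cell or one of its 8 adjacent cells; scanning
// that 3x3 block and testing squared distance <= tau^2 gives the exact
// count (no approximation) in expected O(K) for bounded local density.
//
// Counts exclude the point itself (d_ii = 0 is not a neighbour) unless
// include_self is set.

// [[Rcpp::export(name = ".neighbor_counts_grid")]]
IntegerVector neighbor_counts_grid(NumericVector x, NumericVector y,
                                   double tau, bool include_self = false) {
  const int k = x.size();
  IntegerVector counts(k);
  if (k == 0) return counts;
  const double tau2 = tau * tau;

  double xmin = *std::min_element(x.begin(), x.end());
  double ymin = *std::min_element(y.begin(), y.end());

  std::vector<int> cx(k), cy(k);
  int ncx = 0, ncy = 0;
  for (int i = 0; i < k; ++i) {
    cx[i] = (int)std::floor((x[i] - xmin) / tau);
    cy[i] = (int)std::floor((y[i] - ymin) / tau);
    if (cx[i] + 1 > ncx) ncx = cx[i] + 1;
    if (cy[i] + 1 > ncy) ncy = cy[i] + 1;
  }

  // bucket points by cell with a counting sort
  const long long ncells = (long long)ncx * ncy;
  std::vector<int> cell(k);
  std::vector<int> start(ncells + 1, 0);
  for (int i = 0; i < k; ++i) {
    cell[i] = cy[i] * ncx + cx[i];
    ++start[cell[i] + 1];
  }
  for (long long c = 0; c < ncells; ++c) start[c + 1] += start[c];
  std::vector<int> order(k);
  {
    std::vector<int> cursor(start.begin(), start.end() - 1);
    for (int i = 0; i < k; ++i) order[cursor[cell[i]]++] = i;
  }

  for (int i = 0; i < k; ++i) {
    int n = 0;
    for (int dy = -1; dy <= 1; ++dy) {
      int gy = cy[i] + dy;
      if (gy < 0 || gy >= ncy) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        int gx = cx[i] + dx;
        if (gx < 0 || gx >= ncx) continue;
        long long c = (long long)gy * ncx + gx;
        for (int p = start[c]; p < start[c + 1]; ++p) {
          int j = order[p];
          double ddx = x[i] - x[j], ddy = y[i] - y[j];
          if (ddx * ddx + ddy * ddy <= tau2) ++n;
        }
      }
    }
    counts[i] = include_self ? n : n - 1;  // own cell always contains i
  }
  return counts;
}
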