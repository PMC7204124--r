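#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Cumulative DTW cost table.
//
// constraint: 0 = steps {(i-1,j), (i,j-1), (i-1,j-1)}
//             1 = steps {(i-1,j-1), (i-2,j-1), (i-1,j-2)}
// boundary:   0 = standard (only the virtual cell (0,0) has cost 0; every
//                 other out-of-table predecessor is +Inf)
//             1 = literal (every cell with i < 1 or j < 1 has cost 0)
// local_cost: 0 = |x - y|, 1 = (x - y)^2
//
// Cells unreachable under the chosen step set stay +Inf.
// [[Rcpp::export(name = ".dtw_table")]]
NumericMatrix dtw_table_cpp(NumericVector a, NumericVector b,
                            int constraint, int boundary, int local_cost) {
  const int M = a.size(), N = b.size();
  NumericMatrix D(M, N);
  const double inf = R_PosInf;

  // predecessor deltas (di, dj), listed in backtracking preference order
  std::vector<int> di, dj;
  if (constraint == 0) { di = {1, 1, 0}; dj = {1, 0, 1}; }
  else                 { di = {1, 2, 1}; dj = {1, 1, 2}; }

  for (int i = 0; i < M; ++i) {
    for (int j = 0; j < N; ++j) {
      double diff = a[i] - b[j];
      double d = (local_cost == 0) ? std::abs(diff) : diff * diff;
      double best = inf;
      for (size_t s = 0; s < di.size(); ++s) {
        int pi = i - di[s], pj = j - dj[s];
        double prev;
        if (pi >= 0 && pj >= 0) {
          prev = D(pi, pj);
        } else if (boundary == 1) {
          prev = 0.0;                       // literal: zero outside the table
        } else {
          prev = (pi == -1 && pj == -1) ? 0.0 : inf;  // standard entry at (0,0)
        }
        if (prev < best) best = prev;
      }
      D(i, j) = (best == inf) ? inf : best + d;
    }
  }
  return D;
}

// 8-connected component labeling of a binary matrix (0 background).
// Labels are positive integers assigned in raster-scan order of first visit.
// [[Rcpp::export(name = ".label_components8")]]
IntegerMatrix label_components8_cpp(IntegerMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next_label = 0;
  std::vector<int> stack;
  stack.reserve(256);

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next_label;
      lab(r, c) = next_label;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            int r2 = rr + dr, c2 = cc + dc;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            if (mask(r2, c2) != 0 && lab(r2, c2) == 0) {
              lab(r2, c2) = next_label;
              stack.push_back(r2 + c2 * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}
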