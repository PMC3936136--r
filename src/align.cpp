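#include <Rcpp.h>
using namespace Rcpp;

// Local alignment with affine gaps over a precomputed reward matrix.
//
// Recurrences (query along rows i, database along columns j; 1-based over
// an implicit zero boundary row/column):
//   M[i,j] = max( M[i-1,j-1] + reward[i,j], E[i,j], F[i,j], 0 )
//   E[i,j] = max( E[i,j-1] - g_e, M[i,j-1] - g_o )   (horizontal gap)
//   F[i,j] = max( F[i-1,j] - g_e, M[i-1,j] - g_o )   (vertical gap)
// E/F are -Inf on the boundary: a gap cannot be extended before it is
// opened. Cells clamp at zero (local alignment).

// Score-only scan keeping two rows; argmax ties broken by smallest i,
// then smallest j (first occurrence in row-major order).
// [[Rcpp::export(name = ".dp_score")]]
List dp_score(NumericMatrix reward, double gap_open, double gap_extend) {
  const int n = reward.nrow(), m = reward.ncol();
  const double ninf = -std::numeric_limits<double>::infinity();
  std::vector<double> prev(m + 1, 0.0), curr(m + 1, 0.0), F(m + 1, ninf);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    double E = ninf;
    curr[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      E = std::max(E - gap_extend, curr[j - 1] - gap_open);
      F[j] = std::max(F[j] - gap_extend, prev[j] - gap_open);
      double v = prev[j - 1] + reward(i - 1, j - 1);
      v = std::max(v, E);
      v = std::max(v, F[j]);
      v = std::max(v, 0.0);
      curr[j] = v;
      if (v > best) { best = v; bi = i; bj = j; }
    }
    std::swap(prev, curr);
  }
  return List::create(_["score"] = best, _["i"] = bi, _["j"] = bj);
}

// Full-matrix variant for backtracking and as the quadratic-space oracle.
// Returns M, E, F as (n+1) x (m+1) matrices including the zero boundary.
// [[Rcpp::export(name = ".dp_matrix")]]
List dp_matrix(NumericMatrix reward, double gap_open, double gap_extend) {
  const int n = reward.nrow(), m = reward.ncol();
  const double ninf = -std::numeric_limits<double>::infinity();
  NumericMatrix M(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  std::fill(E.begin(), E.end(), ninf);
  std::fill(F.begin(), F.end(), ninf);
  std::fill(M.begin(), M.end(), 0.0);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E(i, j) = std::max(E(i, j - 1) - gap_extend, M(i, j - 1) - gap_open);
      F(i, j) = std::max(F(i - 1, j) - gap_extend, M(i - 1, j) - gap_open);
      double v = M(i - 1, j - 1) + reward(i - 1, j - 1);
      v = std::max(v, E(i, j));
      v = std::max(v, F(i, j));
      v = std::max(v, 0.0);
      M(i, j) = v;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  return List::create(_["M"] = M, _["E"] = E, _["F"] = F,
                      _["score"] = best, _["i"] = bi, _["j"] = bj);
}
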