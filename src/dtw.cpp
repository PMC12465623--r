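#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Subsequence dynamic time warping of a template y (length m) against a
// signal x (length n) with free start and end. Uses the symmetric step
// pattern (diagonal, vertical, horizontal) and a per-path Sakoe-Chiba band:
// a cell (i, j) is reachable from a predecessor whose propagated start
// column s only if |(j - s) - i| <= band (0-based), i.e. the alignment may
// not drift more than `band` columns off the diagonal anchored at its own
// start. Start columns, path lengths and the column aligned to a designated
// anchor row (typically the template peak) are propagated along with the
// cost, so no backtracking is required.
//
// Returns, for every possible end column j (1-based):
//   cost[j]   accumulated alignment cost of the best path ending at (m, j)
//   length[j] number of cells on that path (for cost normalisation)
//   start[j]  signal column where the path begins
//   anchor[j] signal column aligned with template row `anchor_row`
// Unreachable ends carry cost = +Inf and start = 0.
// [[Rcpp::export]]
List dtw_subsequence_scan(NumericVector x, NumericVector y, int band,
                          int anchor_row) {
  const int n = x.size(), m = y.size();
  const double INF = R_PosInf;
  if (n < 1 || m < 1) stop("empty input to dtw_subsequence_scan");
  if (anchor_row < 1 || anchor_row > m) stop("anchor_row out of range");

  std::vector<double> Dp(n), Dc(n), Pp(n), Pc(n);
  std::vector<int> Sp(n), Sc(n), Ap(n), Ac(n);

  for (int j = 0; j < n; ++j) {  // template row 0: free start
    Dp[j] = std::fabs(x[j] - y[0]);
    Pp[j] = 1.0;
    Sp[j] = j + 1;
    Ap[j] = (anchor_row == 1) ? j + 1 : 0;
  }

  for (int i = 1; i < m; ++i) {
    for (int j = 0; j < n; ++j) {
      double best = INF, bl = 0.0;
      int bs = 0, ba = 0;
      // diagonal (i-1, j-1)
      if (j > 0 && Dp[j - 1] < INF &&
          std::abs((j - (Sp[j - 1] - 1)) - i) <= band) {
        best = Dp[j - 1]; bl = Pp[j - 1]; bs = Sp[j - 1]; ba = Ap[j - 1];
      }
      // vertical (i-1, j)
      if (Dp[j] < INF && std::abs((j - (Sp[j] - 1)) - i) <= band &&
          Dp[j] < best) {
        best = Dp[j]; bl = Pp[j]; bs = Sp[j]; ba = Ap[j];
      }
      // horizontal (i, j-1)
      if (j > 0 && Dc[j - 1] < INF &&
          std::abs((j - (Sc[j - 1] - 1)) - i) <= band && Dc[j - 1] < best) {
        best = Dc[j - 1]; bl = Pc[j - 1]; bs = Sc[j - 1]; ba = Ac[j - 1];
      }
      if (best == INF) {
        Dc[j] = INF; Pc[j] = 0.0; Sc[j] = 0; Ac[j] = 0;
      } else {
        Dc[j] = best + std::fabs(x[j] - y[i]);
        Pc[j] = bl + 1.0;
        Sc[j] = bs;
        Ac[j] = (i + 1 == anchor_row) ? j + 1 : ba;
      }
    }
    std::swap(Dp, Dc); std::swap(Pp, Pc);
    std::swap(Sp, Sc); std::swap(Ap, Ac);
  }

  NumericVector cost(n), plen(n);
  IntegerVector scol(n), acol(n);
  for (int j = 0; j < n; ++j) {
    cost[j] = Dp[j]; plen[j] = Pp[j]; scol[j] = Sp[j]; acol[j] = Ap[j];
  }
  return List::create(_["cost"] = cost, _["length"] = plen,
                      _["start"] = scol, _["anchor"] = acol);
}
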