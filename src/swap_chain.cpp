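#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Sequential-swap randomization of a binary matrix: repeatedly pick 2 random
// rows and 2 random columns; if they form a checkerboard submatrix
// ([[1,0],[0,1]] or [[0,1],[1,0]]) flip it, which preserves all row and
// column totals. Optionally records the C-score after every accepted swap
// past a burn-in, updating the pairwise co-occurrence counts incrementally.
// Uses R's RNG so results are reproducible under set.seed().
//
// Returns list(matrix = final matrix, scores = recorded C-scores,
//              proposals = total proposals tried).
// [[Rcpp::export]]
List cpp_swap_chain(IntegerMatrix mat, int burn_in, int n_record,
                    double max_tries) {
  IntegerMatrix m = clone(mat);
  int S = m.nrow(), n = m.ncol();
  if (S < 2 || n < 2) stop("matrix must be at least 2 x 2");

  // row totals and pairwise co-occurrence counts
  std::vector<double> R(S, 0.0);
  for (int i = 0; i < S; ++i)
    for (int j = 0; j < n; ++j) R[i] += m(i, j);
  std::vector<std::vector<double> > SS(S, std::vector<double>(S, 0.0));
  for (int i = 0; i < S; ++i)
    for (int k = i + 1; k < S; ++k) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) s += m(i, j) * m(k, j);
      SS[i][k] = SS[k][i] = s;
    }
  double total = 0.0;  // sum over unordered pairs of (R_i - S_ik)(R_k - S_ik)
  for (int i = 0; i < S; ++i)
    for (int k = i + 1; k < S; ++k)
      total += (R[i] - SS[i][k]) * (R[k] - SS[k][i]);
  const double n_pairs = (double)S * (S - 1) / 2.0;

  NumericVector scores(n_record);
  long n_target = (long)burn_in + n_record;
  long accepted = 0;
  double tries = 0.0, total_tries = 0.0;

  while (accepted < n_target) {
    ++total_tries;
    if (++tries > max_tries)  // per-accepted-swap proposal budget
      stop("no checkerboard swap found within `max_tries` proposals");
    int a = (int)(unif_rand() * S); if (a == S) a = S - 1;
    int b = (int)(unif_rand() * (S - 1)); if (b >= a) ++b;
    int c = (int)(unif_rand() * n); if (c == n) c = n - 1;
    int d = (int)(unif_rand() * (n - 1)); if (d >= c) ++d;
    int ac = m(a, c), ad = m(a, d), bc = m(b, c), bd = m(b, d);
    if (!((ac == 1 && bd == 1 && ad == 0 && bc == 0) ||
          (ac == 0 && bd == 0 && ad == 1 && bc == 1)))
      continue;
    // flip the 2x2 checkerboard; row/column totals are conserved
    m(a, c) = 1 - ac; m(a, d) = 1 - ad;
    m(b, c) = 1 - bc; m(b, d) = 1 - bd;
    // incremental update: only pairs involving rows a or b change, and the
    // (a,b) pair itself is unchanged (both products at c and d stay 0)
    double da = (1.0 - 2.0 * ac);  // change of m(a,c); m(a,d) changes by -da
    for (int k = 0; k < S; ++k) {
      if (k == a || k == b) continue;
      double mkc = m(k, c), mkd = m(k, d);
      double dSa = da * (mkc - mkd);
      double dSb = -da * (mkc - mkd);
      total -= (R[a] - SS[a][k]) * (R[k] - SS[a][k]);
      total -= (R[b] - SS[b][k]) * (R[k] - SS[b][k]);
      SS[a][k] += dSa; SS[k][a] = SS[a][k];
      SS[b][k] += dSb; SS[k][b] = SS[b][k];
      total += (R[a] - SS[a][k]) * (R[k] - SS[a][k]);
      total += (R[b] - SS[b][k]) * (R[k] - SS[b][k]);
    }
    ++accepted;
    tries = 0.0;
    if (accepted > burn_in && n_record > 0)
      scores[accepted - burn_in - 1] = total / n_pairs;
  }
  return List::create(_["matrix"] = m, _["scores"] = scores,
                      _["proposals"] = total_tries);
}
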