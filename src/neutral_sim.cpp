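#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// draw a taxon index from the cumulative metacommunity distribution
static inline int draw_cum(const std::vector<double>& cum) {
  double u = unif_rand() * cum.back();
  return std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
}

// Moran-type neutral dynamics for independent local communities coupled to a
// metacommunity p. One generation = N death/replacement events. A death is
// replaced by an immigrant (taxon ~ p) with probability m_event, otherwise by
// a copy of a uniformly chosen surviving local individual. Uses R's RNG.
// [[Rcpp::export]]
IntegerMatrix cpp_neutral_sim(NumericVector p, int n_samples, int N,
                              double m_event, int n_generations) {
  int S = p.size();
  std::vector<double> cum(S);
  double acc = 0.0;
  for (int k = 0; k < S; ++k) { acc += p[k]; cum[k] = acc; }

  IntegerMatrix out(S, n_samples);
  std::vector<int> ind(N);
  for (int s = 0; s < n_samples; ++s) {
    for (int i = 0; i < N; ++i) ind[i] = draw_cum(cum);
    long events = (long)n_generations * N;
    for (long e = 0; e < events; ++e) {
      int dead = (int)(unif_rand() * N);
      if (dead == N) dead = N - 1;
      if (unif_rand() < m_event) {
        ind[dead] = draw_cum(cum);
      } else {
        int parent = (int)(unif_rand() * (N - 1));
        if (parent >= dead) ++parent;  // parent drawn from the N-1 survivors
        ind[dead] = ind[parent];
      }
    }
    for (int i = 0; i < N; ++i) out(ind[i], s) += 1;
  }
  return out;
}
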