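#include <Rcpp.h>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Degree-preserving Metropolis target swaps (0-based node ids).
// With probability g a proposed swap of the targets of two random edges is
// accepted only if it moves the in-degree covariance sum(k_src * k_tgt) in the
// requested direction (mode = +1 assortative, -1 disassortative); with
// probability 1 - g it is accepted unconditionally.  Swaps that would create a
// self-loop or a duplicate edge are rejected and still count as attempts.
// [[Rcpp::export]]
List rewire_cpp(IntegerVector from, IntegerVector to, IntegerVector indeg,
                int nnode, int mode, double g, double n_attempts,
                bool allow_neutral = false) {
  R_xlen_t E = from.size();
  std::vector<int> f(from.begin(), from.end()), t(to.begin(), to.end());
  std::unordered_set<int64_t> eset;
  eset.reserve((size_t)(2 * E));
  for (R_xlen_t e = 0; e < E; ++e)
    eset.insert((int64_t)f[e] * nnode + t[e]);
  double accepted = 0.0;
  for (double it = 0.0; it < n_attempts; it += 1.0) {
    int e1 = (int)(unif_rand() * E), e2 = (int)(unif_rand() * E);
    if (e1 >= E) e1 = E - 1;
    if (e2 >= E) e2 = E - 1;
    if (e1 == e2) continue;
    int i = f[e1], j = f[e2], m1 = t[e1], m2 = t[e2];
    if (m1 == m2) continue;
    bool do_swap = true;
    if (g >= 1.0 || unif_rand() < g) {
      double ki = indeg[i], kj = indeg[j], mi = indeg[m1], mj = indeg[m2];
      double cur = ki * mi + kj * mj, alt = ki * mj + kj * mi;
      if (allow_neutral && cur == alt)
        do_swap = true;
      else
        do_swap = (mode > 0) ? (cur < alt) : (cur > alt);
    }
    if (!do_swap) continue;
    if (i == m2 || j == m1) continue;  // would create self-loop
    int64_t k1 = (int64_t)i * nnode + m2, k2 = (int64_t)j * nnode + m1;
    if (eset.count(k1) || eset.count(k2)) continue;  // duplicate edge
    eset.erase((int64_t)i * nnode + m1);
    eset.erase((int64_t)j * nnode + m2);
    eset.insert(k1);
    eset.insert(k2);
    t[e1] = m2;
    t[e2] = m1;
    accepted += 1.0;
  }
  return List::create(_["to"] = IntegerVector(t.begin(), t.end()),
                      _["accepted"] = accepted);
}
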