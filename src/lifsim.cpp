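#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Forward-Euler simulation of a delayed-pulse-coupled LIF network.
//
// Each neuron receives an independent Poisson train of rate s * nu_thr
// (events generated by exponential waiting times, each event depolarizing by
// J) plus recurrent J-pulses delivered through per-edge delays rounded to the
// integration grid (minimum one step).  During the refractory period the
// membrane is clamped to vr and all input is discarded.  Node ids 0-based.
// [[Rcpp::export]]
List simulate_lif_cpp(IntegerVector from, IntegerVector to,
                      NumericVector delay_ms, int nnode, double s,
                      double nu_thr, double J, double tau, double tau_ref,
                      double theta, double vr, double dt, double t_measure,
                      double burn_in) {
  R_xlen_t E = from.size();
  // CSR adjacency by source
  std::vector<int> off(nnode + 1, 0), tgt(E), dstep(E);
  for (R_xlen_t e = 0; e < E; ++e) off[from[e] + 1]++;
  for (int i = 0; i < nnode; ++i) off[i + 1] += off[i];
  {
    std::vector<int> pos(off.begin(), off.end() - 1);
    for (R_xlen_t e = 0; e < E; ++e) {
      int p = pos[from[e]]++;
      tgt[p] = to[e];
      dstep[p] = std::max(1, (int)std::lround(delay_ms[e] / dt));
    }
  }
  int D = 1;
  for (R_xlen_t e = 0; e < E; ++e) D = std::max(D, dstep[e] + 1);

  std::vector<double> buf((size_t)nnode * D, 0.0), V(nnode), next_ext(nnode);
  std::vector<int> refr(nnode, 0), counts(nnode, 0);
  double lam = s * nu_thr * dt;  // external events per step
  for (int i = 0; i < nnode; ++i) {
    V[i] = vr + unif_rand() * (theta - vr);
    next_ext[i] = lam > 0.0 ? exp_rand() / lam : R_PosInf;
  }
  int ref_steps = (int)std::lround(tau_ref / dt);
  double decay = 1.0 - dt / tau;
  int steps_total = (int)std::lround((burn_in + t_measure) / dt);
  int burn_steps = (int)std::lround(burn_in / dt);

  for (int ts = 0; ts < steps_total; ++ts) {
    int slot = ts % D;
    for (int i = 0; i < nnode; ++i) {
      double inc = buf[(size_t)i * D + slot];
      buf[(size_t)i * D + slot] = 0.0;
      int nev = 0;
      while (next_ext[i] < ts + 1.0) {
        ++nev;
        next_ext[i] += exp_rand() / lam;
      }
      if (refr[i] > 0) {  // inputs discarded while refractory
        --refr[i];
        V[i] = vr;
        continue;
      }
      V[i] = V[i] * decay + inc + J * nev;
      if (V[i] >= theta) {
        if (ts >= burn_steps) ++counts[i];
        for (int p = off[i]; p < off[i + 1]; ++p)
          buf[(size_t)tgt[p] * D + (ts + dstep[p]) % D] += J;
        V[i] = vr;
        refr[i] = ref_steps;
      }
    }
  }
  NumericVector rates(nnode);
  for (int i = 0; i < nnode; ++i) rates[i] = counts[i] / t_measure * 1000.0;
  return List::create(_["counts"] = IntegerVector(counts.begin(), counts.end()),
                      _["rates_hz"] = rates);
}
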