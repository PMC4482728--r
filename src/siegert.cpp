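#include "special.h"

#include <Rcpp.h>
using namespace Rcpp;

namespace lifnet {

static const GaussLegendre GL32(32);

static double gl_erfcx_linear(double lo, double hi) {
  double c = 0.5 * (hi + lo), hw = 0.5 * (hi - lo), s = 0.0;
  for (size_t i = 0; i < GL32.x.size(); ++i)
    s += GL32.w[i] * erfcx_pos(c + hw * GL32.x[i]);
  return s * hw;
}

double int_erfcx(double x1, double x2) {
  if (x2 <= x1) return 0.0;
  double out = 0.0;
  double cut = std::min(x2, std::max(x1, 1.0));
  if (cut > x1) out += gl_erfcx_linear(x1, cut);
  if (x2 > cut) {
    // v = exp(w): integrand v * erfcx(v), slowly varying in w; composite GL
    double wlo = std::log(cut), whi = std::log(x2);
    int npan = (int)std::ceil((whi - wlo) / 2.0);
    double dw = (whi - wlo) / npan;
    for (int p = 0; p < npan; ++p) {
      double a = wlo + p * dw, c = a + 0.5 * dw, hw = 0.5 * dw, s = 0.0;
      for (size_t i = 0; i < GL32.x.size(); ++i) {
        double v = std::exp(c + hw * GL32.x[i]);
        s += GL32.w[i] * v * erfcx_pos(v);
      }
      out += s * hw;
    }
  }
  return out;
}

double siegert(double mu, double sigma, double tau, double tau_ref,
               double theta, double vr) {
  if (sigma <= 0.0) {  // noiseless limit
    if (mu <= theta) return 0.0;
    return 1.0 / (tau_ref + tau * std::log((mu - vr) / (mu - theta)));
  }
  double a = (vr - mu) / sigma, b = (theta - mu) / sigma;
  if (b > 25.0) return 0.0;  // rate below ~1e-260 / ms
  double I;
  if (b <= 0.0) {
    I = int_erfcx(-b, -a);
  } else if (a >= 0.0) {
    I = 2.0 * (std::exp(b * b) * dawson(b) - std::exp(a * a) * dawson(a)) -
        int_erfcx(a, b);
  } else {
    I = int_erfcx(0.0, -a) + 2.0 * std::exp(b * b) * dawson(b) -
        int_erfcx(0.0, b);
  }
  return 1.0 / (tau_ref + tau * SQRTPI * I);
}

}  // namespace lifnet

// [[Rcpp::export]]
NumericVector siegert_rate_cpp(NumericVector mu, NumericVector sigma,
                               double tau, double tau_ref, double theta,
                               double vr) {
  R_xlen_t n = mu.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = lifnet::siegert(mu[i], sigma[i], tau, tau_ref, theta, vr);
  return out;
}

// Relaxation of the coupled k-population rate equations
//   tau_x dr_k/dt = -r_k + phi_k(r, s)
// to a fixed point.  Nkk[k, kp] is the mean number of inputs a k-class neuron
// receives from kp-class neurons; ext = nu_thr * s (1/ms); rates in 1/ms.
// [[Rcpp::export]]
List relax_rates_cpp(NumericMatrix Nkk, double ext, NumericVector init,
                     double J, double tau, double tau_ref, double theta,
                     double vr, double tau_x, double dt, double tol,
                     int max_steps) {
  int m = Nkk.nrow();
  std::vector<double> r(init.begin(), init.end()), phi(m);
  double resid = R_PosInf;
  int step = 0;
  bool conv = false;
  double alpha = dt / tau_x;
  while (step < max_steps) {
    ++step;
    resid = 0.0;
    for (int k = 0; k < m; ++k) {
      double drive = ext;
      for (int kp = 0; kp < m; ++kp) drive += Nkk(k, kp) * r[kp];
      double mu = J * tau * drive;
      double sig2 = J * mu;
      double sig = sig2 > 0.0 ? std::sqrt(sig2) : 0.0;
      phi[k] = lifnet::siegert(mu, sig, tau, tau_ref, theta, vr);
      double d = std::fabs(phi[k] - r[k]);
      if (d > resid) resid = d;
    }
    for (int k = 0; k < m; ++k) r[k] += alpha * (phi[k] - r[k]);
    if (resid < tol) {
      conv = true;
      break;
    }
  }
  return List::create(_["rates"] = NumericVector(r.begin(), r.end()),
                      _["converged"] = conv, _["steps"] = step,
                      _["residual"] = resid);
}
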