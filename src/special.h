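#ifndef LIFNET_SPECIAL_H
#define LIFNET_SPECIAL_H

#include <cmath>
#include <vector>

namespace lifnet {

static const double SQRTPI = 1.7724538509055160273;

// scaled complementary error function erfcx(x) = exp(x^2) erfc(x), x >= 0
inline double erfcx_pos(double x) {
  if (x <= 5.0) return std::exp(x * x) * std::erfc(x);
  // asymptotic series, relative error < 1e-9 for x > 5
  double ix2 = 1.0 / (2.0 * x * x);
  double term = 1.0, sum = 1.0;
  for (int k = 1; k <= 14; ++k) {
    term *= -(2 * k - 1) * ix2;
    sum += term;
  }
  return sum / (x * SQRTPI);
}

// Dawson function F(x) = exp(-x^2) int_0^x exp(t^2) dt, x >= 0.
// Sampling-series evaluation (h = 0.25) below x = 6, asymptotic series above.
inline double dawson(double x) {
  if (x == 0.0) return 0.0;
  if (x > 6.0) {
    double ix2 = 1.0 / (2.0 * x * x);
    double term = 1.0, sum = 1.0;
    for (int k = 1; k <= 15; ++k) {
      term *= (2 * k - 1) * ix2;
      sum += term;
    }
    return sum / (2.0 * x);
  }
  const double h = 0.25;
  int nlo = (int)std::ceil((x - 7.5) / h);
  int nhi = (int)std::floor((x + 7.5) / h);
  if (nlo % 2 == 0) ++nlo;
  double sum = 0.0;
  for (int n = nlo; n <= nhi; n += 2) {
    double d = x - n * h;
    sum += std::exp(-d * d) / n;
  }
  return sum / SQRTPI;
}

// Gauss-Legendre nodes/weights on [-1, 1]
struct GaussLegendre {
  std::vector<double> x, w;
  explicit GaussLegendre(int n) : x(n), w(n) {
    for (int i = 0; i < (n + 1) / 2; ++i) {
      double z = std::cos(M_PI * (i + 0.75) / (n + 0.5)), z1, pp;
      do {
        double p1 = 1.0, p2 = 0.0;
        for (int j = 0; j < n; ++j) {
          double p3 = p2; p2 = p1;
          p1 = ((2 * j + 1) * z * p2 - j * p3) / (j + 1);
        }
        pp = n * (z * p1 - p2) / (z * z - 1.0);
        z1 = z;
        z = z1 - p1 / pp;
      } while (std::fabs(z - z1) > 1e-15);
      x[i] = -z; x[n - 1 - i] = z;
      w[i] = 2.0 / ((1.0 - z * z) * pp * pp);
      w[n - 1 - i] = w[i];
    }
  }
};

// int_{x1}^{x2} erfcx(v) dv for 0 <= x1 <= x2; log substitution on the 1/v tail
double int_erfcx(double x1, double x2);

// Siegert first-passage rate of an LIF neuron (1/ms). mu, sigma in mV,
// tau/tau_ref in ms. Returns 0 when the rate underflows (threshold more than
// ~25 noise SDs above the mean input).
double siegert(double mu, double sigma, double tau, double tau_ref,
               double theta, double vr);

}  // namespace lifnet

#endif
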