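---
title: "Mean-field rates and information transfer in degree-correlated LIF networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean-field rates and information transfer in degree-correlated LIF networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifnet)
```

## The model

`lifnet` computes stationary activity of a directed, purely excitatory
network of leaky integrate-and-fire neurons.  The membrane potential of
neuron $i$ obeys

$$\tau \frac{dV_i}{dt} = -V_i + R I_i(t),$$

with threshold $\Theta$, reset $V_r$, absolute refractory period
$\tau_{ref}$, and delta-pulse synapses of amplitude $J$ delivered after a
per-edge delay.  Each neuron additionally receives an independent external
Poisson train; its rate is the stimulus, normalized by
$\nu_{thr} = \Theta/(J\tau)$ so that $s = 1$ marks the point where the mean
external drive alone reaches threshold.

The central approximation is the *k-population density* ansatz: all neurons
of equal in-degree $k$ are statistically exchangeable, and in a large sparse
network their synaptic input is a Gaussian process (diffusion approximation)
with moments

$$\mu_k = J\tau\Big(\nu_{thr}\,s + \sum_{k'} N_{kk'}\,\hat r_{k'}\Big),
  \qquad \sigma_k^2 = J\,\mu_k,$$

where $N_{kk'} = k\,f(k,k')$ is the mean number of in-degree-$k'$ neurons
feeding an in-degree-$k$ neuron.  The stationary rate of each population is
the Siegert first-passage rate

$$\hat r_k = \Big[\tau_{ref} + \tau\sqrt{\pi}
  \int_{(V_r-\mu_k)/\sigma_k}^{(\Theta-\mu_k)/\sigma_k}
  e^{x^2}\big(1+\mathrm{erf}\,x\big)\,dx\Big]^{-1},$$

and the coupled system $\hat r_k = \phi_k(\hat{\mathbf r}, s)$ is solved by
relaxing $\tau_x\,d\hat r_k/dt = -\hat r_k + \phi_k$ to a fixed point.  All
of the topology enters through one matrix, $N_{kk'}$, which can either be
tallied from a concrete graph (`sample_joint_degree()`) or taken from closed
forms (`analytic_kernel()`): independent in/out degrees, equal-in/out
uncorrelated ($f(k,k') = k'P(k')/\langle k\rangle$), maximally assortative
($f = \delta_{kk'}$, the network segregates into same-degree subnetworks) and
maximally disassortative ($k$ paired with $\approx k_{min}k_{max}/k$).

### Assumptions worth keeping in mind

* Populations receive *uncorrelated* Gaussian input — valid for large, sparse,
  asynchronously firing networks; synchronization phenomena are outside the
  model (the random 0–6 ms delays in the simulator exist precisely to
  suppress synchronous cascades, and do not affect stationary rates).
* $\sigma_k^2 = J\mu_k$ encodes shot noise of uniform-amplitude excitatory
  pulses; inhibition is not modeled.
* The refractory bound caps every rate at $1/\tau_{ref}$.

## Parameters, units, defaults

Internal computation uses mV and ms; all reported rates are in Hz.

| parameter | default | meaning |
|---|---|---|
| `tau` | 20 ms | membrane time constant |
| `tau_ref` | 2 ms | refractory period (bounds rates at 500 Hz) |
| `theta` | 20 mV | firing threshold |
| `v_reset` | 10 mV | reset potential |
| `J` | 0.1 mV | synaptic amplitude |
| `alpha`, `k_min`, `k_max` | −2, 10, 500 | in-degree distribution $P(k)\propto k^{\alpha}$ |
| delays | uniform 0–6 ms | per-edge synaptic delay |
| `dt` | 0.01 ms | simulator step |
| `tau_x` | 3 ms | relaxation time constant of the fixed-point solver |

The threshold is a convention: with rates expressed in units of
$\nu_{thr}$ and $\sigma^2 = J\mu$, the stationary solutions depend on the
voltage scale only through $\Theta$ and $\Theta - V_r$.  We adopt the
classic sparse-network parameterization $\Theta = 20$ mV, $V_r = 10$ mV
(exposed as ordinary `neuron_params()` fields), under which the uncorrelated
$\alpha=-2$ network loses sustained activity at $s \approx 0.8$ and the
heavier-tailed $\alpha=-1.7$ network at $s \approx 0.55$ — the reference
behavior this package reproduces.  Note $\nu_{thr} = 10$ events/ms (10 kHz):
stimuli are strong Poisson streams of weak (0.1 mV) pulses.

## Network construction

Degree sequences are drawn i.i.d. from the truncated power law; by default
each node's out-degree equals its in-degree (as reported for biological
wiring diagrams, and necessary for same-degree subnetworks to be closed).
Stub pairing is delegated to `igraph::sample_degseq()`; self-loops and
duplicate edges are then *removed*, so realized degrees sit slightly below
their targets.  All degree classes downstream are recomputed from the
realized graph — the mean-field method never sees the target sequence.

Degree correlations are imposed by Metropolis target swaps: two random edges
exchange targets, which preserves every in- and out-degree.  With probability
$g$ a swap is accepted only if it moves $\sum_{edges} k_{src} k_{tgt}$ in the
requested direction; with probability $1-g$ it is accepted unconditionally.
Swaps that would create a self-loop or duplicate edge are rejected *and count
as attempts* — allowing them and de-duplicating afterwards would change the
degree sequences, which the chain must preserve exactly.  Correlation
strength is measured by the Pearson coefficient of in-degrees across link
ends, normalized by the variance of the excess in-degree distribution
$Q^{in}_k = (k+1)P(k+1)/\sum_k kP(k)$.  Two properties of this estimator
matter in practice:

* Because $Q^{in}$ derives from the *node* degree distribution while the
  covariance is tallied over *links*, the coefficient carries a small
  positive finite-size offset and can slightly exceed 1 on a maximally
  assortative finite graph.  The plain link-sample Pearson correlation is
  returned alongside (`p_edge`) as a diagnostic; on the reference
  configuration-model network the excess-normalized estimator, not
  `p_edge`, reproduces the reference value ($p \approx -0.004$).
* Maximal assortativity is size-limited: a $k$-class can only wire onto
  itself if it has more than $k$ members, i.e. $k^3 \lesssim N Z$.  At
  $N = 10^4$ the maximal-rewiring plateau is $p \approx 0.85$; the same
  chain reaches $0.978$ at $N = 3\times10^4$ and $>0.99$ at $N = 10^5$.
  Desk-scale tests that demand the large-$N$ plateau value at $N = 10^4$
  will therefore fail for structural, not algorithmic, reasons.

`rewire_to_plateau()` runs blocks of swaps until $p$ stops moving;
`rewire_to_assortativity()` steers $p$ to a target with adaptively sized,
bidirectional blocks (the first few thousand swaps on an uncorrelated
network move $p$ very quickly, so fixed large blocks overshoot).

## Numerical choices

* **Siegert integrand.**  $e^{x^2}(1+\mathrm{erf}\,x)$ overflows immediately;
  it is evaluated as $\mathrm{erfcx}(-x)$ for $x<0$ and as
  $2e^{x^2} - \mathrm{erfcx}(x)$ for $x\ge 0$, with the $e^{x^2}$
  antiderivative expressed through the Dawson function
  ($\int_0^b e^{x^2}dx = e^{b^2}F(b)$).  `erfcx` uses the standard library
  `erfc` below $x=5$ and an asymptotic series above; the Dawson function uses
  a sampling series ($h = 0.25$) below $x=6$ and an asymptotic series above.
  The smooth $\int \mathrm{erfcx}$ pieces use 32-point Gauss–Legendre panels
  (log-transformed on the $1/x$ tail).  Agreement with adaptive quadrature is
  at the $10^{-8}$ level; when the threshold sits more than 25 noise SDs
  above the mean the rate underflows and is returned as exactly 0.
* **Fixed point.**  Explicit Euler on the relaxation equation with
  $dt = \tau_x/3$, converged when the residual
  $\max_k|\phi_k(\hat r) - \hat r_k|$ falls below $10^{-6}$ Hz, with a
  $2000\,\tau_x$ time budget.  One population per distinct realized
  in-degree (up to 491 classes); no binning is applied.
* **Branch selection.**  The system is bistable below threshold.  Response
  curves are computed by *downward* continuation from $s = 1.2$, each solve
  initialized from its neighbor and the first from 80 % of the refractory
  bound — this tracks the stable upper branch, which is the operating regime
  analyzed throughout.  Upward continuation from a quiescent state is
  available and tracks the lower branch; results always record which branch
  they carry.
* **Extinction threshold.**  Mean rate below 0.1 Hz counts as quiescent; the
  threshold is reported as the midpoint of the bracketing stimulus interval
  with the grid step (default 0.02) as its uncertainty.
* **Simulator.**  Forward Euler at 0.01 ms; delays round to the grid with a
  one-step minimum; external Poisson input is generated by exponential
  waiting times; during refractoriness the membrane is clamped and inputs are
  discarded (the conventional choice — the alternative of accumulating input
  during the dead time is not modeled).  Initial voltages are uniform on
  $[V_r, \Theta)$ and a 200 ms burn-in precedes counting.

## Information transfer

The network output is the mean rate of $n$ randomly sampled neurons
(default $n = 5000$).  For a stimulus prior uniform on $(0,1)$ the
stimulus–response mutual information is computed two ways:

* **Direct quadrature** (default) of
  $I = \int ds\,dr\,P(s)P(r|s)\log_2[P(r|s)/P(r)]$ with Gaussian
  conditionals of variance $\sigma^2(s)/n$.  Stimuli for which the network
  is quiescent respond with the exact symbol $r = 0$: they form an atom of
  mass $w$ in the response marginal and contribute $w\log_2(1/w)$.  This
  treatment is exact for the mixed discrete/continuous channel and is why
  direct quadrature is the primary method — the uncorrelated network below
  threshold *is* such a channel.
* **Small-noise expansion** $I = H - H_{noise}$, with the response entropy
  from the change of variables $P(\hat r) = P(s)/(d\hat r/ds)$ (central
  differences on the stimulus grid) and
  $H_{noise} = \tfrac12\,\mathbb E\,\log_2[2\pi e\,\sigma^2/n]$.  Flat
  segments of the response curve are assigned to discrete symbols whose
  masses enter the entropy as $-\sum_a w_a \log_2 w_a$; the differential and
  discrete parts combine into the entropy of the mixed distribution.  An
  everywhere-flat curve is rejected — the expansion does not apply.

$\sigma^2(s)$ is the $P(k)$-weighted variance of the per-class rates (the
weighting across populations is a modeling choice; the empirical class
proportions are used for sampled kernels, so weights and kernel always come
from the same graph).  Both estimators reproduce a linear-Gaussian channel's
closed form to $10^{-3}$ bits, and they agree within a few percent on smooth
monotone curves at large $n$.

`assortativity_sweep()` chains the whole pipeline over a grid of Pearson
levels.  At desk scale ($N = 10^4$, readout $n = 5000$) the resulting
$I(p)$ profile is unimodal: sensitivity to weak stimuli grows with
assortativity (the extinction threshold moves down, the response curve
becomes shallower and more linear), while the firing-rate distribution — and
with it the readout noise entropy — broadens monotonically.  The measured
optima sit at $p^\* \approx 0.59$ for $\alpha = -2$ and
$p^\* \approx 0.39$ for $\alpha = -1.7$: heavier-tailed networks fire more
strongly and need less assortativity.

## What the synthetic generator does and does not emulate

All tests run on synthetic networks from the package's own generator:
truncated power-law in-degrees, equal in/out degree per node, Metropolis-
imposed in-degree correlations, uniform random delays.  This captures the
degree heterogeneity and assortativity of biological circuits but none of
their other structure: no inhibition, no spatial embedding or modularity, no
synaptic weight diversity, no in/out-degree *independence*, no activity-
dependent plasticity.  Passing tests therefore certify the method's internal
consistency (mean-field vs direct simulation, analytic vs sampled kernels),
not the biological fidelity of any particular parameter set.

## Problem sizes used by the test suite

Networks of $N = 10^4$ nodes (~3.8×10^5 edges) are the standard scale for
network-level checks: simulator-vs-theory comparisons at $s = 1.2$ (binned
per-degree-class rates agree within 10 %, typically well under 2 %),
rewiring extremes, and the information sweeps.  Unit tests use graphs of
$10^2$–$3\times10^3$ nodes and hand-enumerable toys.  Full-size
($N = 10^5$) runs are supported and were used to verify the size scaling of
the assortative plateau, but are not part of the default suite.

## Known limitations

* Purely excitatory networks; extending to excitatory–inhibitory populations
  requires separate population classes per sign.
* Stationary analysis only: the relaxation dynamics is a solver, not a model
  of transients; no finite-size corrections to the diffusion approximation.
* The lower (unstable) branch and full bifurcation structure are not traced;
  only upper- and lower-branch continuations are provided.
* The excess-distribution Pearson estimator inherits the finite-size offset
  discussed above; comparisons across very different degree ranges should
  use matched estimators.
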