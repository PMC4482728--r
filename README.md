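# lifnet

Firing rates and information transfer of degree-correlated networks of
leaky integrate-and-fire (LIF) neurons.

## The problem

Cortical connectivity is strongly heterogeneous: in-degrees of neurons span
orders of magnitude, and the in-degrees at the two ends of a synaptic link
are often correlated (assortativity — hubs wiring to hubs).  Both features
shape how a recurrent excitatory network responds to a weak common stimulus.
`lifnet` is for computational neuroscientists who want to compute the
stationary activity of such networks *without* simulating every neuron, and
to quantify how degree correlations change the network's ability to transmit
sub-threshold signals.

## The model

Each neuron follows LIF dynamics, `tau dV/dt = -V + R I(t)`, fires when `V`
reaches the threshold `theta`, and resets to `v_reset` for a refractory time
`tau_ref`.  Synapses deliver delta pulses of size `J` after a delay.  Every
neuron also receives an independent external Poisson train whose rate is the
stimulus, expressed in units of `nu_thr = theta / (J tau)` (the rate at which
mean drive alone reaches threshold, so `s < 1` is sub-threshold).

The package's core is a *k-population mean-field method*: neurons are grouped
into populations by in-degree `k`, and under the diffusion approximation each
population's stationary rate obeys the coupled self-consistent system

    r_k = phi(mu_k, sigma_k),        k = k_min .. k_max
    mu_k = J tau (nu_thr s + sum_k' N_kk' r_k'),   sigma_k^2 = J mu_k

where `phi` is the Siegert first-passage transfer function and `N_kk'` — the
*joint degree distribution*, the mean number of in-degree-`k'` neurons
synapsing into an in-degree-`k` neuron — carries all of the network topology.
`N_kk'` can be sampled from any directed graph or taken from closed forms
(uncorrelated, maximally assortative, maximally disassortative ensembles).
The system is relaxed to its stable fixed point; downward continuation in `s`
tracks the active upper branch of the bistable regime.

Around this core the package provides: truncated power-law degree
distributions; directed configuration-model generation (equal in- and
out-degree per neuron) with degree-preserving Metropolis rewiring toward a
prescribed Pearson in-degree correlation `p`; a direct LIF simulator used as
a verification oracle; and the mutual information between a uniformly
distributed sub-threshold stimulus and the noisy population-rate readout
(`n` sampled neurons, Gaussian noise of variance `sigma^2 / n`).

## Worked example

```r
library(lifnet)
set.seed(1)

dist <- truncated_powerlaw(-2, 10, 500)
degree_moments(dist)
#>       mean   variance
#>   38.42124 3283.02068

net <- configuration_model(sample_degree_sequence(dist, 10000))
pearson_in_degree_correlation(net)$p
#> [1] -0.005224457

params <- neuron_params()          # tau 20 ms, theta 20 mV, J 0.1 mV, ...
kern  <- sample_joint_degree(net)
sol   <- solve_selfconsistent(kern, s = 1.2, params)
sol
#> Stationary k-population rates at s = 1.2 (357 classes)
#>   range [47.850, 273.403] Hz, residual 9.7e-07 Hz (converged)

curve <- response_curve(analytic_kernel(dist, "uncorrelated_equal_inout"),
                        seq(0, 1.2, by = 0.02), params)
stimulus_threshold(curve, epsilon = 0.1)$s_star
#> [1] 0.79
```

The threshold means the uncorrelated network loses self-sustained activity
once the stimulus drops below ~0.8 `nu_thr`; low-degree populations stop
firing first and their failure cascades through the network.  Rewiring the
same graph assortatively (`rewire_to_assortativity(net, 0.6)`) moves this
extinction point to much weaker stimuli, at the price of a broader (noisier)
firing-rate distribution — `assortativity_sweep()` quantifies the resulting
trade-off as a mutual-information profile over `p`, which peaks at an
intermediate assortativity.

A thin command-line wrapper over the same functions is installed under
`inst/cli/lifnet.R` (subcommands `net-generate`, `net-rewire`, `net-stats`,
`mf-response`, `sim-run`, `mi-sweep`).

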