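# plastnet

Cortical circuits show *metastable* activity: ensembles of neurons hold
roughly constant firing rates for a few hundred milliseconds, then switch
to another pattern at seemingly random times. Clustered spiking networks —
groups of excitatory neurons with mutually potentiated synapses — produce
exactly this dynamics, but how such structure can *emerge from a local
learning rule* and then survive its own ongoing plasticity is the hard
part. plastnet is an R package for studying that question: it simulates
deterministic recurrent networks of exponential integrate-and-fire (EIF)
neurons whose E→E synapses follow a fully local, voltage-based plasticity
rule with a BCM-like adaptive threshold, and ships the training and
perturbation protocols, the metastability analysis, and the mean-field
theory needed to understand the result. It is aimed at computational
neuroscientists who want a compact, reproducible, tibble-native workbench
for plasticity-and-metastability experiments.

## The model in brief

Membrane dynamics (EIF):

$$\dot V_i = \frac{-(V_i - V_L) + \Delta_T e^{(V_i - V_T)/\Delta_T}}{\tau_m}
  + h_i^{E,syn} + h_i^{I,syn} + h_i^{st} + h_i^{ext},$$

with a spike at $V \ge V_{peak}$, reset to $V_r$, and exponentially
filtered synaptic input ($\tau_{syn}\dot h = -h + \sum w\,\delta$).

Plasticity (per presynaptic spike, E→E only, weights clamped at 0):

$$\Delta w_{ij} = A_{LTP}\,e^{-\beta w_{ij}^2}[\tilde v_i - \theta_i]_+
  - A_{LTD}[\theta_i - \tilde v_i]_+,
\qquad
\tau_\theta\dot\theta_i = \theta_a\tanh[g(-\theta_i + \tilde v_i +
  \gamma\tilde s_i)],$$

where $\tilde v_i$ low-pass filters the exponential voltage term and
$\tilde s_i$ the postsynaptic spike train. The sliding threshold makes a
single spike plasticity-neutral, repeated co-activation potentiating, and
prolonged activation depressing — clusters form under training, then the
network self-tunes onto the instability line where memory states
spontaneously reactivate. The mean-field side computes the EIF transfer
function $F(\mu, s)$ from the stationary Fokker–Planck equation and maps
the active-cluster phase over the intra-cluster weight moments
$(\mu, \sigma)$, with the accessibility bound
$\sigma_{max}(\mu) = \sqrt{w_{max}\mu - \mu^2}$.

See `vignette("plastnet-methods")` for the full account of models,
estimators and numerical choices.

## Worked example

Train a 1000-neuron network on four stimuli for two simulated minutes,
then watch one minute of ongoing activity:

```r
library(plastnet)

cfg <- network_config(N = 1000, Q = 4, f = 0.1, seed = 1)
net <- build_network(cfg)
cluster_stats(net$clusters)
#>       Q   N_E     f mean_size sd_size frac_nonresponsive frac_responsive
#> 1     4   800   0.1      83.5    9.29              0.639           0.361

sched <- training_schedule(net$clusters, session_ms = 120000,
                           amplitude = cfg$h_st,
                           seed = substream_seed(cfg$seed, "schedule"))
training <- run_session(net, sched)
ongoing  <- run_session(training$network, empty_schedule(60000),
                        resume = training)
glance(ongoing)
#>       t0  t_end plasticity n_spikes rate_E rate_I      w0    w1
#> 1 120000 180000 TRUE         117801  0.386   8.27 0.00292 0.557
```

Sixty presentations lift the shared-stimulus weight class from its initial
0.005 mV to `w1 = 0.56` mV while unrelated synapses stay at
`w0 = 0.003` mV — the block structure of learned clusters. The ongoing
epoch already reactivates those memories spontaneously:

```r
states <- detect_states(overlap_series(ongoing$spikes, net$clusters,
                                       ongoing$t0, ongoing$t_end))
duration_stats(states)
#>   n_segments n_complete mean_ms sd_ms    cv exp_diagnostic
#> 1         10         10      48  75.1  1.56          0.565
```

Ten hidden-state reactivations in one minute, identified as overlap
excursions above 0.5. (At this reduced scale dwell times are short and
broader than exponential; the full 10-minute protocol of
`scripts/reproduce_basic.R` gives ~190 ms mean durations and over a
thousand reactivations.) The mean-field solver explains the pre-training
baseline:

```r
solve_rates(meanfield_config(N_E = 800, N_I = 200, Q = 10),
            ansatz = "uniform")
#> <plastnet_rate_solution> ansatz: uniform (converged)
#>     E     I
#> 0.497 9.269
```

i.e. ~0.5 spikes/s spontaneous excitatory activity, matching the
simulation. `mf_landscape()` maps where active-cluster solutions exist,
`autoplot()` methods draw rasters with overlaps, weight-class
trajectories, dwell-time histograms and the landscape, and
`run_experiment()` / `inst/scripts/plastnet` stage whole seeded pipelines
to plain-text artifacts.

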