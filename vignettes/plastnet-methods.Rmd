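---
title: "Models and methods behind plastnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind plastnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(plastnet)
```

plastnet simulates how a recurrent spiking network can *learn* the clustered
synaptic structure that produces metastable activity — the switching among
transient firing-rate states seen across cortex — using a plasticity rule
that is fully local: each synapse sees only its own weight, presynaptic
spikes, and the postsynaptic membrane state. This vignette describes the
models, the estimators, and the numerical and design choices, in enough
detail to judge what the package's tests do and do not establish.

## Neuron and network model

Each neuron is an exponential integrate-and-fire (EIF) unit,

$$\dot V = \frac{-(V - V_L) + \Delta_T e^{(V - V_T)/\Delta_T}}{\tau_m}
 + h^{E,syn} + h^{I,syn} + h^{st} + h^{ext},$$

with a spike registered when $V \ge V_{peak} = 25$ mV followed by a reset to
$V_r = 0$ mV. The exponential term gives a soft spike-initiation threshold
at $V_T = 20$ mV with sharpness $\Delta_T = 1$ mV. Synaptic input is a
weighted delta train low-pass filtered with $\tau_{syn}$ (3 ms for
excitatory, 2 ms for inhibitory inputs): every arriving spike of efficacy
$w$ adds a jump $w/\tau_{syn}$ to the corresponding filter. There is no
refractory period, no adaptation current and no short-term plasticity —
deliberately, so that metastability cannot be inherited from any of those
mechanisms.

The standard ("basic") network has $N_E = 800$ excitatory and $N_I = 200$
inhibitory neurons, random connectivity with $p_{EE} = 0.2$ and 0.5
elsewhere, and initial efficacies $w_{EE} = 0.005$, $w_{EI} = -0.34$,
$w_{IE} = 0.54$, $w_{II} = -0.46$ mV. Signs are fixed by population (Dale's
law); only E→E synapses are plastic and they are clamped at zero from
below, so the sign structure survives any amount of plasticity. All
defaults are in `network_config()`, `neuron_params()` and
`plasticity_params()` and can be serialised to YAML (`write_config()`).

## The plasticity rule

A change in an E→E efficacy is triggered by a presynaptic spike and its
direction is set by the postsynaptic neuron:

$$\Delta w = A_{LTP}\, e^{-\beta w^2}\, [\tilde v - \theta]_+ \;-\;
  A_{LTD}\, [\theta - \tilde v]_+ .$$

$\tilde v$ is a 50 ms low-pass filter of the exponential voltage term — it
barely moves during subthreshold fluctuations and rises sharply when the
neuron spikes. The attenuation $e^{-\beta w^2}$ ($\beta = 0.1$ mV$^{-2}$)
prevents strong synapses from growing without bound. The threshold
$\theta$ adapts,

$$\tau_\theta \dot\theta = \theta_a \tanh\!\big[g(-\theta + \tilde v +
  \gamma \tilde s)\big],$$

with $\tilde s$ a 1 s low-pass of the postsynaptic spike train. Because the
tanh saturates, the *effective* time scale of $\theta$ grows with the size
of the excursion it is chasing: for the normalised equation
$\tau_\theta\dot\theta = \tanh(-\theta + \Delta)$ the time to reach
$\Delta/2$ is

$$T_{1/2}(\Delta) = \tau_\theta \ln\frac{\sinh\Delta}{\sinh(\Delta/2)}
\;\to\; \tau_\theta\ln 2 \ (\Delta \ll 1), \qquad
T_{1/2} \approx \tau_\theta\Delta/2 \ (\Delta > 3),$$

implemented in `t_half()` and verified in the tests against direct ODE
integration. Note that the closed form belongs to the normalised equation
(unit gain and amplitude); with a large gain $g$ the threshold ramps
linearly instead and the $\ln 2$ limit does not apply.

The consequences, all covered by tests: a silent neuron has
$\theta \approx \tilde v$ and experiences no net plasticity; a single spike
opens a brief LTP window followed by a longer LTD window whose expected net
effect is far below the trained-weight scale; sustained firing raises
$\gamma\tilde s$, pulls $\theta$ above $\tilde v$, and converts
potentiation into depression. That LTP→LTD transition is what caps cluster
self-excitation without any homeostatic add-on.

## Construction, protocols and what the generator emulates

Stimulus clusters are independent Bernoulli draws: each of $Q$ stimuli
targets each excitatory neuron with the coding level $f$ (0.1 in the basic
network), giving overlapping clusters of mean size $fN_E = 80$, a
non-responsive fraction $(1-f)^Q \approx 0.35$, and a probability
$1-(1-f)^{Q-1} \approx 0.61$ that a member of one cluster belongs to
others. Training presents one uniformly drawn stimulus every 2 s for
500 ms at drive $h^{st} = 0.5$ mV/ms; the session lasts $Q \times 60$ s so
every stimulus is seen about 30 times regardless of network size.
Perturbation sessions draw event times from a Poisson process (mean
interval 10 s, 200 ms events) in three flavours — fresh random targets,
a 50/50 mix with a second fixed stimulus set, or the second set only
(remapping). Set-2 stimuli are sampled with replacement.

These generators emulate the *statistics* of sensory drive (sparse random
ensembles, overlap, Poisson timing), not any particular sensory pathway:
real stimuli are correlated in time and feature space, real connectivity
is distance- and type-dependent, and real networks see ongoing
neuromodulation. Passing tests therefore establish the self-organisation
and self-tuning mechanism under the stated statistical conditions, not a
quantitative match to any recorded circuit.

Scaling regimes (`scale_network()`): `linear` keeps the cluster size at 80
($Q = N/100$, $f = 1/Q$), `sqrt` grows both cluster count and size
($Q = \sqrt{N/10}$); both coincide with the basic network at $N = 1000$.
Under the linear regime the per-synapse drift scales as $1/N$, which
`weight_change_rate()` exposes by collapsing $N\,\Delta w_C$ curves.

## Analysis definitions

Rates are causal boxcar counts (50 ms window, 10 ms grid by default — the
window resolves few-hundred-ms states while smoothing single spikes; both
are parameters, and dwell-time statistics do depend on them). The overlap
of stimulus $q$ is the rate-weighted activity fraction of its cluster,
$m_q = \sum_i \eta_{qi}\nu_i / \sum_i \nu_i \in [0, 1]$, defined as 0 when
the network is silent. A memory state is active while $m_q > 0.5$
(strict); maximal above-threshold runs become segments with no smoothing
or debouncing, segments touching the recording edge are censored and
excluded from statistics, and `duration_stats()` reports
$|\mathrm{sd}/\mathrm{mean} - 1|$ as an exponentiality diagnostic. Weight
classes: a plastic synapse is class 1 when its neurons share at least one
stimulus, class 0 otherwise; class membership is computed against the
training cluster map unless a new map is passed explicitly (so
"remapping" bookkeeping is a deliberate user action).

## Mean-field theory

For theory we use a simplified network: non-overlapping uniform clusters,
intra-cluster weights i.i.d. with mean $\mu$, sd $\sigma$ and support
$[0, w_{max} = 4]$ mV, inter-cluster weights fixed at a small constant
(default: the pre-training $w_{EE}$, exposed as `w_minus`). Under the
diffusion approximation the input to each population is white noise whose
mean and variance are linear in the rates (`population_inputs()` reports
all four contributions separately); synapses are treated as instantaneous
for these moments, so the finite $\tau_{syn}$ of simulations is a known
source of quantitative mismatch. The EIF transfer function $F(\mu, s)$ is
computed by backward threshold integration of the stationary Fokker-Planck
flux equations from $V_{peak}$ down to $V_{lb}$ with reinjection at $V_r$
(`eif_rate_fp()`), and the self-consistency $\nu = F(\mu(\nu), s(\nu))$ is
solved by damped fixed-point iteration under either a uniform ansatz or a
one-active-cluster ansatz (`solve_rates()`). The $(\mu, \sigma)$ landscape
masks pairs above $\sigma_{max}(\mu) = \sqrt{w_{max}\mu - \mu^2}$ — no
distribution on $[0, w_{max}]$ can realise them — and reports the
instability line between the phase with and without active-cluster
solutions. Metastable switching lives in a finite band around that line,
and the trained network's $(\bar w_1, \mathrm{sd}\, w_1)$ trajectory
(`weight_moments()`) can be overlaid on it.

## Numerical choices

* Integration: forward Euler at `dt = 0.05` ms; synaptic and spike-trace
  filters use the exact per-step decay factor. A single-neuron rate changes
  by well under 1% when `dt` is halved (tested).
* The exponential term is evaluated with $V$ clipped at $V_{peak}$,
  bounding it at $\Delta_T e^5$ and making the drive into $\tilde v$
  well-defined at spike steps; the same pre-reset value feeds both the
  membrane step and the $\tilde v$ filter.
* Spikes are assigned to the end of the step in which $V \ge V_{peak}$ and
  delivered one step later; there are no explicit axonal delays.
  Plasticity is applied at delivery, reading the postsynaptic filters of
  the current step, and the PSP uses the weight as it was on arrival.
  $\Delta w$ is applied instantaneously, as the delta-train form of the
  rule implies.
* Initial conditions: $V(0) \sim U[V_r, V_T)$ (seeded) to desynchronise
  startup; $\tilde v, \tilde s, \theta$ start at zero, the quiescent fixed
  point. Resumed sessions restore the full state including the synaptic
  filters and the one-step spike buffer, so chained sessions are
  bit-identical to one continuous run (tested).
* One master seed feeds named substreams (connectivity, clusters, initial
  voltages, schedules, perturbations), so plasticity-on/off comparisons
  share identical initial conditions and schedules by construction.
* Fokker-Planck grid: $V_{lb} = -30$ mV, $dV = 0.01$ mV; rates move by
  $<0.1\%$ under grid halving or a 10 mV deeper bound (tested). Fixed
  point: damping 0.1, tolerance $10^{-6}$ spikes/s, bistability probed
  from low and high initial active rates. Iterated rates are capped at
  $10^4$ spikes/s: without a refractory period the fixed point runs away
  at strong self-excitation, and a capped cell marks that regime instead
  of propagating overflow.
* Zero-activity conventions: overlap 0 on a silent grid point; empty state
  lists and empty weight classes are explicit `NA`-marked results, never
  errors.

## Problem sizes used by the tests

The test-suite runs at sizes a laptop handles in minutes: the learning
check trains a 1000-neuron, $Q = 4$ network for two simulated minutes and
records one minute of ongoing activity — enough for a tenfold $w_1/w_0$
separation and several spontaneous reactivations; the transfer-function
check compares Fokker-Planck and Euler-Maruyama rates on a 5×5 moment grid
spanning roughly 1-50 spikes/s (100 s per Monte-Carlo repetition, more
repetitions below 5 spikes/s where counting noise dominates). The full
protocol — basic network, ten minutes of training, ten minutes of ongoing
activity — is `scripts/reproduce_basic.R`; one such run here gave
$w_1 = 0.77$ mV after training, over a thousand reactivations in the
ongoing epoch with mean dwell time ≈ 190 ms, and a slow post-training
$w_1$ decay with stable metastability, with the intra-cluster weight
moments sitting just below the mean-field instability line.

## Known limitations

Dwell-time statistics depend on the rate-estimation window and threshold;
right after training (and at $N = 1000$) the dwell-time distribution is
broader than exponential (sd/mean above 1) and mean durations sit below
the values reached after hours of simulated relaxation in larger networks.
The mean-field theory ignores cluster overlap and finite synaptic time
constants and is stationary — it locates phases, not transition rates.
Simulations are exactly reproducible only for a fixed package version,
compiler and dt, since floating-point spike times feed back into the
dynamics.
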