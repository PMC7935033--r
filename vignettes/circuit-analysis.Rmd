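---
title: "Simulating and analyzing perturbed neural circuits with spikecircuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing perturbed neural circuits with spikecircuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikecircuit)
```

## The scientific problem

Cypin (cytosolic PSD-95 interactor) regulates dendrite growth and the
synaptic localization of the PSD-95 scaffold. Overexpressing it in cultured
hippocampal networks changes synaptic transmission at several scales at
once: AMPA-receptor-mediated conductance, the density of connections
between neurons, and the frequency of spontaneous presynaptic release. The
question this package addresses computationally is how those synaptic-scale
changes combine to reshape circuit-level activity — firing statistics,
population bursting, functional-network organization, and the fidelity with
which a circuit transmits a targeted stimulus.

`spikecircuit` provides the two halves needed to study this in silico:

1. a conductance-based spiking-network simulator with three perturbation
   levers (AMPA conductance scaling, connection-density scaling,
   presynaptic-current scaling) emulating cypin overexpression, and
2. the spike-train, functional-connectivity and graph-metric analysis stack
   that is applied identically to simulated rasters and to microelectrode
   array (MEA) recordings, so model and experiment are compared on the same
   footing.

A synthetic-data module generates raw-trace and raster fixtures with known
ground truth (planted spikes, rates, bursts, correlations, communities), so
every stage of the analysis is testable without recordings.

## The circuit model

The network has 500 leaky integrate-and-fire neurons (400 excitatory, 100
inhibitory) connected probabilistically by class: E-to-E 0.1, E-to-I 0.05,
I-to-E 0.2, I-to-I 0.2. Each membrane follows the Langevin equation

$$C_m \frac{dV}{dt} = -g_m (V - V_L) - I_{syn} - I_{AHP} + I_{pre},$$

integrated by forward Euler with a 0.1-ms step. The synaptic current is
conductance-based,

$$I_{syn} = g_A (V - V_E) + g_N B(V) (V - V_E) + g_G (V - V_I),$$

with exponentially decaying AMPA (2 ms), NMDA (100 ms, Jahr–Stevens
magnesium unblock $B(V)$ at 1 mM) and GABA-A (5 ms) conductances. Although
the printed membrane equation above mentions only the glutamatergic terms,
the network contains inhibitory neurons with stated connection
probabilities, so a GABA-A term is included; the circuit cannot function as
described without it. The after-hyperpolarization current is a
spike-triggered adaptation: a calcium-like variable increments at each
spike and decays exponentially, driving $I_{AHP} = g_{AHP}\,Ca\,(V - V_K)$,
which hyperpolarizes the cell for $V > V_K$. At the default gain the AHP is
a mild brake on sustained firing; population bursts are terminated mainly
by synaptic resource depletion (the slow-recovery short-term depression
below). The external drive has two components: a per-neuron constant bias drawn
once from a Gaussian at initialization (the seeding of external current
inputs), and $I_{pre}$, a Gaussian white-noise presynaptic current whose
increments are scaled by $\sqrt{dt}$, making the noise statistics
independent of the integration step. The distinction matters for the two
experimental levers: the cypin perturbation $I_{pre}\times 2$ doubles the
noise amplitude (it models elevated spontaneous presynaptic release, a
noise process), while the entrainment stimulus doubles the entire external
current — bias and noise — received by the stimulated input neurons.

All synapses are modulated by short-term plasticity in the
utilization/resource (Tsodyks–Markram) form — resources deplete with each
release and recover with $\tau_{rec}$ — and excitatory-excitatory synapses
additionally carry pair-based spike-timing-dependent plasticity with
exponential timing windows, additive updates, and weights clipped to
$[0, w_{max}]$.

### Parameter choices

Most quantitative constants in this family of culture models are
conventions of the modeling literature rather than per-study measurements,
so this package pins every value in one documented place,
`model_parameters()`, and treats that set as part of the package's
definition of the model. Membrane constants (20/10-ms time constants,
$-70$ mV rest, $-50$ mV threshold, 2/1-ms refractory periods) and receptor
kinetics follow the standard recurrent-culture-model conventions. The
remaining free amplitudes — the synaptic conductances, adaptation
strength, and the external-current bias and noise — were calibrated once,
as a set, to put the unperturbed network in the regime that mature
dissociated cultures show on MEAs: low tonic background firing of well under 1 Hz per
neuron punctuated by recurrent synchronized network bursts, with the burst
rate set by stochastic noise ignition rather than by a deterministic
recovery clock (irregular interburst intervals). That calibration was done
against the qualitative activity regime only and then frozen; every number
the package reports downstream is computed from simulations at this single
parameter set.

Two structural choices deserve explanation:

- **Pure depression by default.** `stp_tau_facil = 0` fixes utilization at
  `U`, giving depression-only short-term plasticity. Depression is the
  dominant short-term process in culture bursting models, where resource
  depletion (together with adaptation) terminates bursts; facilitation is
  available by setting the constant.
- **Balanced STDP.** The potentiation and depression amplitudes are equal
  by default. Pair-based STDP in a dense bursting network otherwise drifts
  the weight distribution systematically even without any stimulus, which
  would confound the entrainment protocol's before/after comparison; with
  balanced amplitudes the weight changes are driven by the causal
  pre-before-post correlations that the stimulus itself induces, which is
  the "conditioning" the protocol is designed to measure.

### Perturbation conditions

`apply_cypin_condition()` encodes the three levers:

| condition | AMPA scale | connection density | presynaptic current |
|---|---|---|---|
| `control` | 1 | 1 | 1 |
| `cypin_oe_1` | 1 | 0.75 | 2 |
| `cypin_oe_2` | 2 | 2 | 2 |

Connection-density scaling multiplies all four class probabilities
uniformly (clipped at 1); AMPA scaling multiplies the AMPA maximal
conductance wherever AMPA is present (E-to-E and E-to-I), leaving NMDA and
GABA untouched; presynaptic-current scaling multiplies the white-noise
amplitude of $I_{pre}$ (the noise process that models spontaneous
presynaptic release), leaving the per-neuron bias to the protocol-level
stimulation.

## The entrainment protocol

`run_entrainment()` reproduces the conditioned-stimulus experiment: 10 s of
stabilization (discarded), 300 s of control, then 300 s of training and
300 s of testing during which the external current received by 1% of the
excitatory neurons (4 "input" neurons, chosen uniformly at random under the
master seed) is doubled. The "output" population is all non-input
excitatory neurons; inhibitory neurons belong to neither population. No
teaching signal exists anywhere: whatever conditioning occurs is carried by
the network's own STDP and short-term plasticity.

Signal fidelity is the ratio of output-population to input-population
firing rate; it is computed in the control phase (where the two populations
are statistically exchangeable, so it sits near 1) and again in the testing
phase. Fold changes compare each population's testing-phase rate to its own
control-phase rate, on population-pooled rates by default (a per-neuron
variant is available via `fold_method`). Pre/post functional networks are
built from the equal-length control and testing windows, so rate-driven
bias in the correlation estimates affects both sides alike.

## The analysis stack

The same path serves recordings and simulations:

- **Filtering** (`bandpass_and_notch`): fourth-order Butterworth band-pass
  20–2000 Hz plus a 60-Hz notch, applied forward-backward (zero-phase) so
  spike peak times are not shifted — a phase shift would bias
  cross-correlation lags downstream. The implementation reflection-pads the
  trace to suppress boundary transients.
- **Spike detection** (`detect_spikes`): per-channel adaptive threshold of
  4.5 noise SDs, the SD estimated per non-overlapping 10-s window as
  MAD/0.6745 — the median-based estimate is robust to the spikes
  themselves contaminating the window. One spike per suprathreshold
  excursion, timed at the absolute maximum; detections closer than 2 ms to
  the previous one are discarded so a multiphasic waveform is counted once.
- **Train statistics** (`train_metrics` and friends): spike rate (count
  over duration), ISI mean and CV (sample SD over mean), Fano factor
  (variance-to-mean of binned counts; the bin width defaults to 1 s and is
  deliberately a visible parameter, since the count distribution is
  bin-width dependent), burstlet rate, and the 75th-percentile
  active-electrode rule with linear-interpolation percentiles.
- **Burst detection.** Two rules, matching how bursts manifest in the two
  kinds of data. Per electrode, a *burstlet* is a run of at least 4 spikes
  with ISIs at most min(100 ms, 1/(4·rate)), extended by peripheral spikes
  at ISIs up to min(200 ms, 1/(3·rate)); the rate-dependent thresholds are
  read as fractions of the electrode's mean ISI, the only dimensionally
  consistent reading of "times the firing rate". Per network, a *network
  burst* is at least 50 spikes of the pooled population inside a sliding
  50-ms window, with overlapping qualifying windows merged; the interburst
  interval is the onset-to-onset difference.
- **Functional connectivity** (`build_functional_network`): spike trains
  binned at 1 ms, normalized cross-correlation evaluated at every integer
  lag within ±20 ms (short-latency interactions only), and the maximum over
  lags taken as the edge weight. Normalization divides by the product of
  the binned vectors' norms, so an exactly lag-shifted copy scores 1; the
  counts are not mean-subtracted by default (the spike-train convention),
  with a Pearson-style variant behind `mean_subtract`. Taking the maximum
  over both lag signs makes the matrix symmetric, matching the undirected
  graph measures applied to it.
- **Graph measures** (`network_metrics`): weighted global efficiency (mean
  inverse shortest-path length with edge length = 1/weight, the standard
  weighted conversion), weighted local efficiency (the efficiency of each
  node's induced neighbourhood subgraph), and Louvain community detection.
  Louvain is stochastic, so it is restarted 100 times by default under
  derived sub-seeds and the partition with the best modularity Q at
  resolution 1 is kept — the minimal reproducible policy. When normalizing
  local efficiency to a baseline, pairs with baseline below 0.001 are
  excluded (`normalize_to_baseline`) to prevent aberrant ratios; the
  exclusion is part of the normalization step, not of the metric.

## The synthetic-data generators

`generate_raster()` draws homogeneous-Poisson background trains, optionally
unioned with compound bursts (Poisson burst onsets, fixed spikes-per-burst
and intra-burst ISI), and optionally correlated within groups through a
shared mother train: each member keeps each mother spike with the sharing
probability (jittered by a Gaussian), topped up with an independent train
so the total rate stays at the specified base rate. This construction has
known Poisson count statistics (Fano factor and ISI CV near 1), an
analytically controllable pairwise correlation, and planted community
structure that the connectivity-plus-Louvain pipeline must recover — which
is exactly what the oracle tests assert. A 2-ms refractory period is
imposed so the analysis side's duplicate-spike rule is exercised but never
confounded.

`generate_trace()` embeds a stereotyped biphasic spike waveform at known
times in Gaussian noise, with an optional 60-Hz hum component, retaining
the ground truth for recall/precision scoring of the detector.

What these generators deliberately do not emulate: electrode drift,
correlated (colored) noise, overlapping spike waveforms from multiple
units, or bursting that modulates spike amplitude. Tests passing on
synthetic data therefore validate the pipeline's logic and thresholds, not
its robustness to every pathology of real recordings.

## Numerical choices and degenerate inputs

- Statistics that are undefined at a given spike count (mean ISI below 2
  spikes, CV below 3, Fano factor with no spikes) are returned as `NA`,
  never silently 0.
- A silent source has undefined correlation; its functional-network edges
  are set to 0 with a warning.
- The percentile in the active-electrode rule is pinned to linear
  interpolation (R's default type 7) for reproducibility.
- The spike-detection threshold falls back to treating a short trace as a
  single window; a trailing window fragment reuses the previous threshold.
- The simulator aborts with a diagnostic on non-finite state or runaway
  activity (a configurable spikes-per-neuron-per-second guard).
- Euler integration at 0.1 ms: the closed-form membrane tests bound the
  global error and verify first-order convergence under step halving.

## Problem sizes

The full entrainment protocol (910 simulated seconds of a 500-neuron
network at 0.1-ms resolution) runs in about a minute per protocol on one
core. The package's own test suite uses scaled-down instances chosen to
keep each statistical check well-powered: 50-neuron circuits for protocol
mechanics, 300-s synthetic rasters for Poisson calibration at 4-SD
tolerance, and replicate condition suites of 2 runs at 100-s analysis
windows — the same instrument as the full-scale analyses, at sizes a
laptop reproduces in minutes.

## Known limitations

- The biophysical constants are a pinned, calibrated set, not a measured
  inventory from any specific culture; quantitative simulation results
  should be read as regime-level (directions and rough magnitudes), not as
  parameter-free predictions.
- In this model class the response to doubling the noise current is set by
  a single per-neuron transfer function, so the network-wide response to a
  global noise doubling (the cypin conditions) and the response of a few
  stimulated neurons (the entrainment protocol) are tightly coupled: a
  parameter set that makes the stimulated-input response large also makes
  the global-perturbation folds large. The default parameters favour the
  entrainment regime; stronger slow adaptation (`g_ahp`, `tau_ca`)
  compresses the global folds at the cost of the stimulated response, and
  both regimes cannot be matched quantitatively at once.
- Synaptic inputs are not weighted by dendritic location; the model's
  neurons are points.
- The functional-connectivity edge is undirected by construction; no
  directed or lag-resolved inference is attempted.
- The in vitro arm of the study design (CNQX dose-response, spike sorting
  of waveforms) is out of scope: the pipeline accepts such data in its
  standard raster format but does not reproduce culture-specific values.

## A worked example

```{r example, eval = FALSE}
# a small circuit, simulated and pushed through the full analysis path
cfg <- simulation_config(seed = 1)
sim <- run_simulation(cfg)
metrics <- train_metrics(sim$raster)
bursts <- detect_network_bursts(sim$raster)
fn <- build_functional_network(sim$raster)
nm <- network_metrics(fn, n_repeats = 100, seed = 1, local = FALSE)

# the replicate condition suite, normalized to control
suite <- run_condition_suite(cfg, n_replicates = 2, graph = FALSE)
suite$normalized

# the entrainment protocol
pr <- run_entrainment(cfg, condition = "control")
c(pre = pr$fidelity_pre, post = pr$fidelity_post,
  fold_input = pr$fold_input, fold_output = pr$fold_output)
```
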