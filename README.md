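# spikecircuit

Simulation and analysis of how synaptic-scale perturbations — modeled on
cypin (cytosolic PSD-95 interactor) overexpression — reshape the activity
and functional organization of cultured neural circuits.

Cypin overexpression changes three things at once in a cultured network:
AMPA-receptor-mediated conductance, the density of synaptic connections,
and the frequency of spontaneous presynaptic release. `spikecircuit` makes
those levers explicit in a conductance-based spiking network model and
provides the complete analysis stack that is applied identically to
simulated rasters and to microelectrode-array (MEA) recordings, so
model and experiment can be compared number for number.

## What is inside

**Circuit model** (`simulation_config`, `run_simulation`): 500
leaky integrate-and-fire neurons (400 excitatory, 100 inhibitory),
connected probabilistically by class (E→E 0.1, E→I 0.05, I→E 0.2,
I→I 0.2). Each membrane follows

    C_m dV/dt = -g_m (V - V_L) - I_syn - I_AHP + I_pre

with conductance-based AMPA, NMDA (magnesium unblock) and GABA-A synapses,
a spike-triggered after-hyperpolarization current, and an external drive
`I_pre` of per-neuron bias plus Gaussian white noise. All synapses carry
short-term plasticity (utilization/resource dynamics); E→E synapses carry
pair-based STDP. Integration is forward Euler at 0.1 ms, with a 10-s
stabilization period discarded before a 300-s analysis window.
`apply_cypin_condition()` encodes the perturbations: condition 1
(AMPA ×1, connection density ×0.75, presynaptic noise ×2) and condition 2
(AMPA ×2, density ×2, noise ×2).

**Entrainment protocol** (`run_entrainment`): stabilize → 300 s control →
300 s training → 300 s testing, with the external current received by 1%
of excitatory neurons ("input" neurons) doubled from training onward.
Reports *signal fidelity* — the ratio of output-population to
input-population firing rate — before and after training, and each
population's fold change in rate.

**Spike-train analysis** (`bandpass_and_notch`, `detect_spikes`,
`train_metrics`, `detect_burstlets`, `detect_network_bursts`): zero-phase
Butterworth band-pass (20–2000 Hz) and 60-Hz notch filtering; adaptive
4.5-SD spike detection with robust per-window noise estimates and a 2-ms
duplicate rule; spike rate, ISI mean and CV, Fano factor,
75th-percentile active-electrode selection; per-electrode burstlets
(≥4 spikes, rate-adaptive ISI thresholds) and population network bursts
(≥50 spikes in 50 ms) with interburst intervals.

**Functional connectivity** (`build_functional_network`): 1-ms binning,
maximal normalized cross-correlation within ±20 ms as the (undirected)
edge weight.

**Graph measures** (`network_metrics`): weighted global efficiency,
weighted local efficiency, Louvain communities (best modularity Q over 100
restarts at resolution 1).

**Synthetic data** (`generate_raster`, `generate_trace`): Poisson rasters
with optional planted bursts, pairwise correlation and community
structure; multichannel voltage traces with planted spike waveforms and
mains hum — every downstream stage is testable against known ground truth.

## A worked example

```r
library(spikecircuit)

cfg <- simulation_config(seed = 1)          # the 500-neuron control network
pr  <- run_entrainment(cfg, condition = "control", graph = FALSE)
pr
#> <protocol_result> control | fidelity pre 1.066 -> post 0.228 | fold input 6.80, output 1.45
```

Read: before training the input and output populations are statistically
exchangeable, so fidelity sits near 1. Doubling the external current of
four input neurons entrains the circuit: after training the input
population fires several-fold above its own baseline, far more than the
remaining excitatory neurons do, and fidelity drops well below 1 — the
circuit now responds selectively to the trained stimulus. The fold
magnitudes vary substantially across seeds (input folds from ~7 to ~20 are
typical); `scripts/acceptance.R` averages them over three seeds.

The same raster then flows through the recording-analysis path:

```r
sim <- run_simulation(cfg)
head(train_metrics(sim$raster), 3)          # per-neuron rate, ISI, CV, FF
length(detect_network_bursts(sim$raster))   # population bursts in 300 s
fn <- build_functional_network(sim$raster)
network_metrics(fn, local = FALSE, seed = 1)
```

## Command line

A thin CLI over the same functions lives at `inst/scripts/spikecircuit-cli`
(subcommands `simulate`, `analyze`, `connect`, `graph`, `entrain`,
`suite`), each reading a YAML config and writing delimited-text tables
plus a run manifest.

## Scope

The package does not perform spike sorting (waveform clustering), directed
connectivity inference, or CNQX pharmacology; in vitro dose-response
values require the original cultures and are out of scope — the pipeline
merely accepts such recordings in its standard raster/trace formats. See
the methods vignette (`vignettes/circuit-analysis.Rmd`) for the model's
assumptions, parameter provenance and known limitations.
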