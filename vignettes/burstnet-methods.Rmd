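---
title: "Modelling network bursts in excitatory cultures: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling network bursts in excitatory cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(burstnet)
```

# The problem

Cultured excitatory networks grown on micro-electrode arrays (MEAs) fire in
synchronous *network bursts* whose recurrence rate — the peak burst
frequency — shifts when single-neuron intrinsic properties change, for
example in Rett-syndrome models where MECP2 loss alters voltage-gated
Na^+^/K^+^ currents, input resistance, capacitance and resting potential.
`burstnet` provides the two computational halves needed to study this link:

1. a spiking-network simulator of adaptive leaky integrate-and-fire (AdIF)
   neurons whose genotype-level parameters can be swapped and scanned, and
2. the MEA analysis pipeline that reduces raw extracellular voltage or
   spike trains to a single per-source number, the sub-1 Hz peak of a
   surrogate-normalized power spectrum.

Because every stage is driven by explicit parameter sets and seeds, in
silico "drop-out" experiments can attribute a network-level change to a
named subset of single-neuron parameters.

# The neuron and network model

Each neuron obeys

$$C_m \dot V = g_L (E_L - V) + g_e (E_e - V) - w, \qquad
  \tau_w \dot w = a (V - E_L) - w,$$

with conductance decay $\tau_e \dot g_e = -g_e$. When $V \ge V_{th}$ the
neuron spikes: $V \to V_r$, $w \to w + b$, and every postsynaptic target's
conductance jumps by $w_e$. Units are pF, nS, mV, pA and ms throughout.
Networks are fully excitatory, randomly connected with probability $p$
(default 0.05, no self-connections), and driven by 100 external Poisson
synapses per neuron firing at 20 Hz. The reference population is 1000
neurons simulated for 300 s at a 0.1 ms step; a scaled profile (200
neurons, 60 s) is used for scans and tests, with problem sizes stated
below.

Numerical choices: forward Euler for $V$ and $w$ at $dt = 0.1$ ms with the
exact factor $e^{-dt/\tau_e}$ for the conductance; spike detection at end
of step with same-step synaptic delivery and no axonal delay or refractory
period (the displayed equations contain none); initial state $V = E_L$,
$w = 0$, $g_e = 0$, with optional Gaussian jitter on $V$ (off by default).
The Euler error on the closed-form leak and adaptation relaxations is below
1% for time constants of 20 ms and above at this step. Simulations are
bit-reproducible: connectivity, initial conditions and drive all derive
from one seed, and the compiled core consumes R's RNG in exactly the same
order as the pure-R reference engine, so both engines return identical
rasters — this dual-engine equality is itself a test.

## The external drive and the bursting regime

The external weight `w_ext` is configurable independently of the recurrent
weight `w_e` and defaults to 0.26 nS. This places the mean summed drive
(100 synapses × 20 Hz × `w_ext` × $\tau_e$ ≈ 2.6 nS) just *below* the
conductance at which the resting state reaches threshold (≈ 3 nS for the
default membrane constants). Two consequences define the model's operating
regime:

* **Collective, not cellular, rhythm.** Between bursts neurons sit a few
  mV below threshold and fire only on rare Poisson fluctuations; a single
  spontaneous spike is amplified by the recurrent synapses ($w_e$ = 2.5 nS,
  ≈10 synapses per cell at the scaled profile) into a network-wide burst.
  Each burst drives one spike per neuron, the spike-triggered adaptation
  increment $b$ silences the cell, and the network stays quiet until $w$
  decays — so the burst period is set by $\tau_w \ln(b / w_{ig})$, the
  adaptation recovery, plus a stochastic ignition wait.
* **A clean synaptic-blockade control.** With recurrent synapses removed
  ($w_e = 0$, drive untouched) isolated neurons fire only at the rare
  fluctuation rate, their trains carry no rhythm, and the spectral pipeline
  reports no sub-1 Hz peak — the in-silico analogue of the AMPA-antagonist
  (CNQX) control that abolishes network activity in vitro.

Tying `w_ext` to `w_e` (the simplest reading of a fully glutamatergic
culture) is still available via `network_config(w_ext = NULL)`, but at the
scaled population it produces either tonic asynchronous firing or
reverberating states without a stable sub-1 Hz rhythm, so the decoupled
default was adopted.

## Genotype fixtures are calibration constants

The study that motivates this package reports the *directions* of
patch-clamp differences between genotypes but no numeric model constants.
The fixtures in `genotype_fixture()` are therefore versioned calibration
constants, chosen once with `scripts/calibrate-fixtures.R` so that (i)
every directional relation holds (the MECP2-null set has lower `C_m`,
depolarized `E_L`, lower `g_L`, stronger and slower adaptation; the L124W
set differs from wild type only in `g_L` and the adaptation strengths),
and (ii) the simulated peak ordering is NULL < WT < L124W, all below 1 Hz
at the scaled profile:

| set | C_m (pF) | g_L (nS) | E_L (mV) | $\tau_w$ (ms) | a (nS) | b (pA) |
|-----|---------|----------|----------|---------------|--------|--------|
| WT    | 100 | 10.0 | -65.0 | 1000 | 4.0 | 800 |
| NULL  | 90  | 9.9  | -64.9 | 1300 | 5.0 | 1100 |
| L124W | 100 | 9.9  | -65.0 | 1000 | 3.8 | 500 |

Shared constants: $E_e = 0$ mV, $V_{th} = -50$ mV, $V_r = -60$ mV,
$\tau_e = 5$ ms, $w_e = 2.5$ nS. The membrane offsets of the null set are
deliberately small: in this model (as in the study's conclusion) the
frequency difference between genotypes is carried almost entirely by the
adaptation triple $(a, b, \tau_w)$ — the model's representation of the
Na^+^/K^+^ current deficit — which is exactly what the drop-out experiment
then demonstrates. The ignition threshold is steeply sensitive to the
leak/drive balance, so large membrane offsets would move the network
between dynamical regimes rather than shift its frequency smoothly.

Within the operating range ($b \ge 800$ pA at the scaled profile) the peak
frequency is non-increasing in $b$ and in $\tau_w$, the adaptation-driven
slowing at the heart of the model. Below that range bursts become
multi-spike events whose total adaptation load $k \cdot b$ can grow as $b$
shrinks, so the $b$-response is not globally monotone; the fixtures and the
monotonicity test operate in the single-spike range.

# The spectral burst pipeline

Raw voltage (12.5 kHz) is Butterworth band-passed (200–3000 Hz, order 3,
forward–backward for zero phase), spikes are detected where |v| exceeds 6×
a robust noise scale (median absolute deviation / 0.6745, per electrode;
a windowed variant is available), with one event per supra-threshold
excursion at its extremum and a 1 ms dead time. Spike trains are binned to
1 ms binary sequences. Electrodes with fewer than 5 spikes/min are
inactive; a 64-electrode well passes QC with ≥32 active.

Each binary train's Welch PSD (Hann window, segment length
$\min(2^{16}, N)$ samples, 50% overlap, per-segment mean removal) is
divided, bin by bin, by the averaged PSD of randomly permuted copies of
the same train and expressed in dB. Permuting the 1 ms bins preserves the
spike count exactly while destroying all temporal patterning, so the ratio
cancels firing-rate and flat-noise structure; a power floor of $10^{-6}$
times the smallest positive observed power prevents division by zero on
sparse trains. The *peak burst frequency* is the frequency of the global
maximum over all positive frequencies; a result is returned only when that
maximum falls in (0, 1] Hz, otherwise the train is excluded (reason
`peak-outside-band`), never clamped into band.

Three further conventions deal with degenerate inputs:

* a spectrum whose global maximum never exceeds 0 dB is excluded with
  reason `no-patterning` — at or below 0 dB the train nowhere beats its own
  permuted surrogate, i.e. it carries no temporal structure beyond chance,
  which is how the blockade control and near-silent trains are rejected;
* exactly tied maxima resolve to the lowest frequency and set a tie flag;
* the DC bin is never eligible.

A caution documented here because it shapes the tests: an *exactly*
periodic binary train is a Dirac comb whose harmonics all have equal
power, so its "global peak" is numerically ill-posed (scalloping and
surrogate noise pick an arbitrary harmonic). Physiological trains carry
inter-burst jitter that broadens harmonic $k$ roughly as $k^2$, which
concentrates the global maximum at the fundamental. The spectral oracles
therefore use jittered-regular trains (CV ≈ 0.05–0.1), matching both real
data and the synthetic generator.

Per-well and per-population summaries: `population_average_spectrum()`
averages per-source dB spectra (empty sources skipped and counted), and
the per-well summary is the median of included per-electrode peaks.
`normalize_to_isogenic()` reports (median~mut~ − median~wt~)/median~wt~,
negative meaning slower than wild type.

Welch defaults give ≈0.015 Hz resolution on 300 s recordings and ≈0.017 Hz
on 60 s scaled runs — 60 s is the shortest duration at which sub-1 Hz
peaks separated by one bin remain resolvable, which is why the scaled
profile does not go shorter.

# Synthetic MEA data

`synthetic_well_spec()` describes a 64-electrode, 300 s, 12.5 kHz well in
which network bursts recur as a *jittered-regular renewal process*
(intervals Normal with CV ≤ 0.2, truncated at ±3 SD). A Poisson burst
process would have a flat spectrum and make the spectral estimator vacuous
on synthetic data, so the renewal choice is load-bearing and deliberate.
Participating electrodes (probability 0.9 per burst) fire Poisson spikes
at 120 Hz for the 0.3 s burst; background Poisson spiking runs at 1 Hz.
`embed_spikes_in_voltage()` adds a fixed ~1 ms biphasic template
(negative-then-positive, unit trough) scaled to 8× the 5 µV Gaussian noise
SD. Ground truth (burst onsets and every spike time) is returned alongside
and is identical to the generated data by construction.

What the generator does *not* emulate: electrode crosstalk, drifting noise
floors, multi-unit waveform diversity, burst-shape adaptation over
development, and inhibitory currents. Passing the recovery contract
(median recovered peak within one frequency bin of the true burst rate on
≥90% of participating electrodes for rates 0.1–0.5 Hz at 8× noise)
therefore shows the pipeline is correct on idealized recordings, not that
it is robust to every artefact of real MEAs.

# Experiments

`run_fit_scan()` scans capacitance against membrane time constant
(realized as $g_L = C_m/\tau_m$; default grids 20–120 pF and 10–60 ms,
spanning plausible patch-clamp values), analyzes every combination with
the same spectral pipeline, and `select_top_fit()` picks the combination
closest to a target peak frequency (ties: smaller seed dispersion, then
lexicographic order, flagged). Scans cache per-combination rows and mark
failed simulations `failed` rather than aborting.

`dropout_swap()` exchanges a named subset between two genotype sets:
`adaptation` = $(a, b, \tau_w)$ — $\tau_w$ belongs with the Na^+^/K^+^
representation because it shapes the adaptation current — and `membrane` =
$(C_m, E_L)$. Subset membership is overridable. `run_dropout_experiment()`
tabulates the six conditions (two pure genotypes plus four swaps) over
replicate seeds (default 3, medians reported). With the shipped fixtures
the null-with-wild-type-adaptation condition recovers the wild-type
frequency to within ~2 frequency bins while the membrane swap stays at the
null frequency, and the reciprocal swaps mirror this — the model's
statement that the intrinsic-current subset, not the passive-membrane
subset, drives the burst-frequency phenotype.

`run_connectivity_scan()` scans subthreshold adaptation (4–10 nS) against
connection probability (0.05–0.35) and summarizes the Spearman sign of
peak frequency against $p$ at each $a$. Scans run the simulator with a
spike budget of 100 Hz per neuron: parameter combinations that leave the
physiological regime for a saturated reverberation state (possible at high
connectivity, where the recurrent conductance grows seven-fold across the
$p$ range) abort immediately and are tabulated as `failed` rather than
simulated to completion. A scaled-profile limitation is
documented here openly: at 200 neurons the low end of the $p$ range leaves
only ~10 recurrent synapses per cell and the network sits in the
single-spike regime, where the burst period is insensitive to the
adaptation *accumulated per burst* and the connectivity trend reported by
the full-scale model (faster bursting at lower connectivity) is not
reproduced reliably; grid points can also fall out of the bursting regime
entirely and are then excluded rather than silently interpolated. The scan
function, its table contract and its summaries are fully exercised by the
test suite; the directional claim itself is assessed at the largest
population the test budget allows and its outcome is reported by the
acceptance tests rather than assumed.

# Problem sizes used by tests

Unit tests run sub-second configurations (25–40 neurons, 0.4–4 s).
Regime-level tests use the scaled profile: 200 neurons, 60 s, 3 seeds,
10 surrogate permutations for single runs and 2 for scans (the dB ratio of
a genuine burst rhythm is 5–25 dB, far above surrogate-count noise). The
end-to-end synthetic recovery uses 12-electrode, 180 s wells at three
burst rates. These sizes were chosen as the smallest at which each
property is stable across seeds.

# Known limitations

* Homogeneous populations: no parameter heterogeneity within a genotype,
  so regime boundaries are sharper than in real cultures.
* No inhibition, plasticity, or conduction delays (absent from the model
  the package implements).
* The scaled profile's sparse in-degree makes the connectivity-scan
  direction unreliable (see above); the fit scan and drop-out experiment
  are calibrated and validated at the scaled profile.
* Fixture values are stand-ins constrained by qualitative directions, not
  fits to recorded data; conclusions about real genotypes require
  re-calibration against recordings.
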