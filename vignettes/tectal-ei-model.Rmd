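---
title: "Modeling and measuring excitation-inhibition interplay in the optic tectum"
author: "tectosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and measuring excitation-inhibition interplay in the optic tectum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tectosim)
```

## The scientific problem

Deep-layer output neurons of the vertebrate optic tectum (superior
colliculus) integrate converging sensory streams — in the lamprey,
vision and electroreception — and project to brainstem gaze centers.
Both afferent systems excite the same output neurons monosynaptically
and, through GABAergic interneurons in the superficial layers, also
recruit disynaptic feedforward inhibition that lags excitation by a few
milliseconds. This conductance sequence explains the classic
multisensory phenomenology: spatiotemporally aligned bimodal stimuli
are enhanced, temporally offset ones are attenuated, and spatially
disparate ones are suppressed through lateral (off-field) inhibition.

`tectosim` packages two things:

1. a conductance-based simulator of this microcircuit that can generate
   every kind of record the experiments use (current-clamp and
   voltage-clamp sweeps, cell-attached spike trains, extracellular
   LFP proxies), and
2. the matching analysis chain — synaptic conductance extraction from
   multi-holding current clamp, PSP-train measurement with decay
   subtraction, temporal-offset curves, rectified-integral LFP
   quantification, and passive-property fitting.

Because the simulator provides exact ground truth, every stage of the
analysis chain is validated by parameter recovery, and the calibrated
default profiles let the full pipeline reproduce the headline
physiological quantities end to end (`reproduce()`).

## The membrane and synapse model

All quantities use a fixed unit system: mV, pA, nS, pF, ms. This makes
the membrane equation unit-consistent without conversion factors
(nS × mV = pA):

$$C \frac{dV}{dt} = -G_\mathrm{rest}(V - E_\mathrm{rest})
  - \sum_s g_s(t)\,(V - E_s) + I_\mathrm{inj},$$

with capacitance derived as \(C = \tau_m / R_\mathrm{in}\). The default
output neuron uses \(\tau_m = 98.8\) ms, \(R_\mathrm{in} = 0.95\)
G\(\Omega\) (so \(C \approx 104\) pF), resting potential \(-68\) mV and
spike threshold \(-43.7\) mV. Spiking, when enabled, is
threshold-reset integrate-and-fire with an absolute refractory period;
disabling it emulates intracellular QX-314 (fast sodium-channel
blockade).

Synaptic conductances are amplitude-normalized bi-exponential kernels

$$g(t) = A\,N\left(e^{-(t-t_0)/\tau_d} - e^{-(t-t_0)/\tau_r}\right),
  \qquad t_0 = t_\mathrm{event} + \ell,$$

with \(N\) chosen so the waveform peak equals \(A\), onset latency
\(\ell\), and reversal potentials fixed at 0 mV (glutamatergic) and
\(-75\) mV (chloride-mediated GABA-A).

**Feedforward inhibition as a rate proxy.** The interneuron-to-output
coupling is not spike-triggered: each afferent pulse contributes one
inhibitory waveform, delayed by `feedforward_lag` (default 7.5 ms, the
midpoint of the observed 5–10 ms range), with amplitude proportional to
the pooled afferent drive of that pulse. The experiments characterize
the inhibition by its conductance waveform and lag rather than by
interneuron spike counts, so a rate proxy represents exactly what is
measured while keeping the model deterministic and cheap. A
`gabazine = TRUE` flag zeroes every inhibitory amplitude.

**Supralinear interneuron recruitment.** Pooled drive from coincident
events of both modalities passes through a power
`inhibitory_recruitment_power` (\(\gamma\)) before scaling the
inhibitory amplitude. With \(\gamma > 1\), bimodal stimulation recruits
disproportionately more inhibition than either modality alone — the
circuit-level consequence of interneurons sitting near spike threshold
— and this is what makes bimodal LFP responses sub-additive while
leaving unimodal protocols untouched (\(\gamma = 1\) in the cellular
profiles).

**Short-term depression** is an explicit per-pulse amplitude sequence
(default 1, 0.75, 0.62, then constant) applied to the afferent drive.
The experiments report only normalized per-pulse amplitudes, so a
dynamical resource model would add parameters without adding testable
structure. Note that the sequence scales *conductances*; the
*voltage* train measured from a simulated sweep depresses more
strongly, because later EPSPs ride a depolarized envelope (reduced
driving force) and face accumulated inhibition. The train tests
therefore assert the qualitative fingerprint (decline over pulses 1–3,
steady state thereafter) rather than the conductance-level factors.

**Numerics.** Integration is exponential Euler with conductances taken
at the step midpoint, `dt = 0.05` ms by default; the scheme is exact
for piecewise-constant inputs (the equilibrium and step-response tests
exploit this) and second-order accurate for smooth kernels. Steps
larger than \(\tau_m/50\) are rejected. All simulations are
deterministic; optional additive Gaussian recording noise is seeded
from the protocol and restores the global RNG state afterwards.

## The extracellular (LFP) model

The deep-layer population signal is modeled in the current-source
approximation: the recorded deflection is the signed sum of synaptic
currents onto the population with driving forces evaluated at rest,

$$\mathrm{LFP}(t) \propto g_e(t)(E_e - E_\mathrm{rest})
  + g_i(t)(E_i - E_\mathrm{rest}),$$

inward (excitatory) current positive. Stimulus strength enters through
a saturating duration-recruitment curve
\(s(d) = d^h / (d^h + d_{50}^h)\) (\(d_{50} = 300\ \mu\)s, \(h = 1.3\))
that maps extracellular pulse durations (50–1000 \(\mu\)s) onto
afferent drive. Off-field stimulation of a spatially disparate column
contributes *only* lateral inhibition, scaled by a modality-specific
weight — the observed suppression asymmetry (strong when a visual
off-field stimulus suppresses an electrosensory on-field response,
negligible in the converse direction) has no established mechanism and
is therefore represented phenomenologically by the two weights.

In the LFP profile the inhibitory kernel decays with the same time
constant as the excitatory one (35 ms). Past the disynaptic lag the
recruited inhibition then cancels a fixed fraction of the excitatory
current; cross-modal suppression is this cancellation at the lateral
weight's operating point, and its ceiling is set by the excitatory
charge that escapes inside the lag window (hence the slower, 6 ms
excitatory rise in this profile).

## The conductance-extraction chain

Given current-clamp sweeps of the same stimulus at two or more holding
levels (the protocols use \(-65/-45/-20\) mV), the chain is:

1. **Rest fit** (`fit_rest`): regress baseline holding currents on
   baseline potentials for \(G_\mathrm{rest}\) and
   \(E_\mathrm{rest}\); fit a single exponential to the holding-step
   charging phase for \(\tau\) and \(C = \tau G_\mathrm{rest}\).
   Baseline "steady" values are the fitted exponential asymptotes, so
   a settle time of ~5\(\tau\) does not bias the fit.
2. **Synaptic current** (`synaptic_current`):
   \(I_\mathrm{syn} = I_\mathrm{inj} - C\,dV/dt -
   G_\mathrm{rest}(V - E_\mathrm{rest})\), with \(dV/dt\) by central
   differences on the simulation grid and no additional smoothing. With
   this sign convention \(I_\mathrm{syn} = g_\mathrm{syn}(V -
   V_\mathrm{rev})\): the per-sample ordinary-least-squares slope of
   \(I_\mathrm{syn}\) against \(V\) across sweeps *is*
   \(g_\mathrm{syn}\), and \(V_\mathrm{rev} = -b_0/g_\mathrm{syn}\)
   from the intercept.
3. **Reversal floor**: \(V_\mathrm{rev}\) is reported `NA` where
   \(g_\mathrm{syn} < 0.05\) nS — the intercept/slope ratio is
   ill-conditioned near zero slope. The floor is a parameter.
4. **E/I decomposition** (`decompose_ei`): with fixed reversals,
   \(g_e = g_\mathrm{syn}(V_\mathrm{rev} - E_i)/(E_e - E_i)\) and
   \(g_i = g_\mathrm{syn} - g_e\). The split is computed directly from
   intercept and slope (\(g_e = (-b_0 - g E_i)/(E_e - E_i)\)), which
   stays well-defined where \(g_\mathrm{syn}\) is near zero; small
   negative excursions are clipped to zero with the raw values
   retained for quality control.
5. **Onsets and lag** (`detect_onsets_and_peaks`): onset is the first
   crossing of 10% of a trace's own peak (the fraction is a
   parameter; the experiments mark onsets graphically without a stated
   rule). Components whose peak stays below 0.01 nS count as absent —
   without that floor, regression noise in a gabazine recording would
   produce a spurious inhibition onset. The analysis window defaults
   to 10 ms before to 100 ms after the stimulus.

Ordinary least squares over *all* available holdings is used; the
source experiments do not state whether two or three holding points per
cell entered their regression, and under the linear model the result is
holding-set independent (a property the test suite checks at 1%).

## PSP, spiking and LFP measurements

* **Decay subtraction** (`measure_psp_train`): for each pulse after the
  first, a single exponential fitted to the 20 ms preceding the pulse
  is extrapolated under the response and subtracted; the amplitude is
  the baseline-to-peak of the residual. The 20 ms window is a
  parameter (the underlying procedure is stated without one). Template
  superposition is recovered within 1% when pulses are at least three
  rise times apart.
* **Offset curves** (`offset_attenuation_curve`): the combined
  first-EPSP amplitude per offset, normalized per sweep to the aligned
  (0 ms) response before any averaging.
* **Spike probability** (`spike_probability`): fraction of
  (sweep, pulse) pairs with at least one spike 0–30 ms after the
  pulse; at most one spike counts per pulse. The simulator emits event
  times directly; a threshold-crossing detector with a 2 ms dead time
  (`detect_spikes`) serves trace-based inputs.
* **Interneuron classes** (`classify_interneuron`): retinal quadrants
  sorted by descending EPSP; `no_inhibition` if all IPSPs fall below a
  1 mV floor, `global_inhibition` if inhibition appears in quadrants
  without excitation, `local_inhibition` otherwise. The floor encodes
  "weak" inhibition, for which no numeric criterion exists.
* **Rectified integrals** (`rectified_integral`): trapezoidal integral
  of the absolute baseline-subtracted trace; baseline is the mean of
  the 50 ms before the first stimulus (the convention is unstated in
  the source experiments), and the default window runs from stimulus
  onset to 300 ms after it. Duration-response tables are normalized to
  the maximal control bimodal response with no monotone smoothing.
* **Passive properties** (`fit_time_constant`, `fit_input_resistance`,
  `fi_curve`, `vi_linearity`): three-parameter single-exponential fits
  (nonlinear least squares initialized log-linearly, iterated once over
  the first 5\(\tau\)); steady-state levels from fitted asymptotes;
  spike counts per 500 ms step with the f–I slope over the first 10
  supra-rheobase points ("lower linear range" is marked only
  graphically in the source; the count of points is a parameter).

## Calibration profiles

Three named profiles carry independently calibrated constants, because
the cellular, extracellular and offset experiments come from different
preparations whose reported population averages are not mutually
consistent under one parameter set.

* `cellular_default` — the excitatory kernel peak is fixed at the
  reported 1.11 nS; excitatory decay (39 ms) and inhibitory amplitude
  (1.635 nS, rise 3.4/decay 31 ms, lag 7.5 ms) are calibrated jointly
  so the *recovered* quantities match their references: composite
  reversal at peak conductance near \(-48.2\) mV, first visual EPSP
  near 12.8 mV, onset lag inside 5–10 ms. The reported mean
  inhibitory peak (0.89 nS) cannot coexist with those three
  constraints under the reported membrane constants, so the inhibitory
  amplitude is the calibration's free variable. EPSP trains are
  measured with the neuron held at the inhibitory reversal
  (\(-75\) mV), which isolates the EPSP from the feedforward IPSP —
  the published protocols hold "at the chloride equilibrium" for the
  same reason.
* Spiking constants: with rest \(-68\) mV, threshold \(-43.7\) mV,
  \(\tau_m\) 98.8 ms and \(R_\mathrm{in}\) 0.95 G\(\Omega\) fixed, the
  refractory period alone can only *flatten* an integrate-and-fire
  f–I curve, so the reset potential (calibrated to \(-52.5\) mV, with
  a 1.2 ms refractory period) is the knob that sets the 0.53 spikes/pA
  lower-range slope. The threshold stimulation intensity T is
  calibrated so unimodal input at T fires time-locked spikes while at
  0.7 T only bimodal input does.
* `lfp_default` — population kernel scale, feedforward weight,
  recruitment power \(\gamma\) and the two lateral weights are
  calibrated to the unisensory ceiling (~55% of maximal bimodal),
  the mean gabazine enhancement of the visual series (~85.5%), and the
  suppression pair (~75% / ~3%).
* `offset_default` — fast, strong population volleys (rise 1/decay
  8 ms) with a temporally concentrated inhibition (rise 2/decay 10 ms)
  whose amplitude sets the ~15% attenuation notch at the disynaptic
  lag; the recovery at long offsets is temporal summation over the
  ~99 ms membrane, which requires the strong-drive (saturating)
  regime.

## What the synthetic data does and does not emulate

The generator reproduces the protocol structure of the experiments:
multi-holding triplets with real charging phases, 10 Hz trains with
depression, duration series with saturating recruitment,
gabazine/QX-314 condition flags, threshold-relative cell-attached
trains, and two-column on/off-field pairs. Fixtures are noiseless by
default — acceptance-style checks are exact parameter recovery, and
noise robustness is exercised separately (additive Gaussian noise,
seeded). It does **not** emulate dendritic filtering (the long
membrane time constant argues for somatic equivalence), conductance
nonlinearities, spike shapes, trial-to-trial variability, series
resistance or space-clamp error (the clamp is ideal, as no correction
is applied in the source analyses), or network topography beyond two
columns. Passing tests therefore demonstrate the correctness of the
analysis chain and the internal consistency of the calibrated model —
not that real recordings satisfy the model's assumptions.

Problem sizes are desk scale throughout: single sweeps are 8,000 to
30,000 samples at 0.05 ms, the duration series is 48 sweeps, and the
full reproduction (`reproduce()`) regenerates every fixture bundle on
disk and completes in well under a minute on one core.

## Reproduction machinery

`reproduce()` rebuilds the complete fixture suite from a seed, reads
every bundle back from disk, runs the analysis chain, and reports each
headline quantity against its calibrated reference with the package's
validation tolerances (2% for parameter recovery, 10% for emergent
calibrated percentages, an upper bound for the onset lag):

```{r, eval = FALSE}
reproduce(seed = 1L)
```

Sweep bundles are plain text (a two-column TSV per sweep, a JSON
sidecar with protocol and units, a manifest with MD5 checksums, 9
significant digits), so bundles diff cleanly and regeneration with the
same seed is byte-identical.

## Known limitations

* The suppression asymmetry is phenomenological (two lateral weights),
  not mechanistic.
* The reported population-average conductance peaks, composite
  reversal and EPSP amplitudes are jointly infeasible for a single
  kernel pair; the calibration commits to the subset listed above and
  leaves the inhibitory peak free.
* The rate-proxy inhibition cannot express interneuron spike failures
  or jitter; protocols that depend on them are out of scope.
* `vi_linearity` flags departures from linearity via \(r^2\) only; the
  impedance drop seen at depolarized potentials in real cells is not
  modeled mechanistically.
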