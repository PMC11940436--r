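---
title: "Neuromorphic motor control decoding: models, parameters and design choices"
author: "mcdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuromorphic motor control decoding: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The decoding problem

A motor control decoder (MCD) turns multichannel electrocorticographic
(ECoG) recordings into movement commands: a categorical movement state per
decoding step, optionally continuous 3D hand-trajectory coordinates, and a
binary *satisfaction* signal describing whether the executed action matched
the user's intent. `mcdecode` implements a neuromorphic decoding chain for
this problem: temporal features extracted from the raw signal drive a
spatially embedded spiking neural network (SNN), and the network's spiking
rates are decoded by an Echo State Network (ESN) whose linear readouts are
trained online. The chain runs pseudo-online: one decoding step per
non-overlapping window of 59 samples (about 100.8 ms at the 585.6 Hz
sampling rate of the planar implants the package emulates), and every
learning rule operates incrementally, window by window.

Because chronically implanted ECoG patients are few and their recordings
private, the package ships a synthetic session generator that reproduces
the *shapes* of three experimental designs — a two-state
idle/walk task ("runner"), a three-state task with two 3D hand
trajectories ("sixdof"), and a five-state task with per-window update
flags ("fivedof") — so the full chain is exercisable and testable without
patient data.

## Temporal features

Two feature families convert a raw window (channels x 59 samples,
microvolts) into non-negative "generating currents":

* **Amplitude shift** (`shiftFeatures()`): each channel is shifted so its
  minimum over the calibration reference maps to zero. Values are
  otherwise unscaled, making the features invariant to per-channel DC
  offsets. The reference is the per-window minimum by default; a fixed
  per-session offset mode exists because the natural reference is a
  recording-specific choice.
* **Squared Morlet transform** (`morletFeatures()`): the squared magnitude
  of the complex Morlet wavelet convolution at a fundamental frequency
  `f0`, evaluated at every sample — a time-resolved band-power estimate.
  The wavelet has `nCycles = 7` cycles under its Gaussian envelope
  (sigma_t = nCycles / (2 pi f0)), a conventional width that balances time
  and frequency resolution; it is exposed in the configuration. "Squared"
  is interpreted as per-sample power, and the per-sample values are kept
  (not pooled per window) so the spiking network sees the within-window
  temporal structure. Edge effects are handled by symmetric reflection of
  the window.

The standard fundamental-frequency bank is 10–150 Hz in steps of 10 Hz
(`frequencyBank()`, 15 members); one decoder model is trained per member
and the members are combined by threshold voting.

## The spiking network

Neurons are leaky integrate-and-fire (LIF):

    dVm/dt = -(Vm - EL)/tau_m + (Isyn + Ie)/Cm

with a spike at `Vm >= Vth`, reset to `vReset` and an absolute refractory
period. Defaults: `Vth = -65 mV`, `tRef = 0 ms`, and — because the
remaining constants are free — conventional values `EL = vReset = -70 mV`,
`tau_m = 10 ms`, `Cm = 250 pF`, placing the threshold 5 mV above rest
(rheobase 125 pA). Integration is forward Euler at `dt = 0.1 ms` (0.01 ms
in the closed-form validation tests); one feature sample is held
piecewise-constant for 1/fs ≈ 1.707 ms. Membrane state persists across
consecutive windows — the simulator is a continuous-time system cut into
windows, not a per-window batch — with a reset available by rebuilding the
network.

Connectivity follows a small-world rule on the 3D neuron coordinates:
`w(i,j) = w0 exp(-d_ij / sigmaD)` up to a cutoff `dCut`, plus sparse
Bernoulli long-range links at the cutoff strength. The default template
places one neuron at each electrode position plus filler neurons on a
jittered grid in the electrode bounding box (64 by default, giving ~100
neurons for a 32-electrode session); an individual coordinate CSV can
replace it. Synapses are delta-current: a presynaptic spike deflects the
target membrane by `w * synapticCharge / Cm` (default 0.1 mV per unit
weight) after a uniform 1 ms delay.

Plasticity is additive nearest-neighbour pair-based STDP with learning
rate `lambda = 0.001`, `tau+ = tau- = 20 ms`, depression/potentiation
asymmetry 1.05 and ceiling `wMax = 2 w0`; weights are clipped to
`[0, wMax]` and structural zeros (absent synapses) never learn. STDP runs
continuously — every window, in training and in decoding — which is the
unsupervised auto-adaptation path of the decoder.

The SNN's readout is the per-window spiking frequency of the
electrode-mapped neurons: spike count divided by the window duration
(`spikeRateFeatures()`).

### Current mapping

Features are z-scored per channel against statistics frozen over a
calibration segment (the first 30 windows by default), clipped to ±4,
offset by `bias = 5.1` and scaled by `gain = 25 pA`. With the default LIF
constants this puts a median feature just above rheobase (~25 Hz in an
isolated neuron), so decreases and increases of band power both move the
rate: at ~100 ms windows the spike count is small (2–6), and an operating
point near rheobase maximises its sensitivity. The calibration pass is run
on a throwaway copy of the network; the main loop then replays the same
windows from the same initial state, so the statistics are causal and the
run remains deterministic.

## The ESN decoder

Reservoir update (leaking rate `a`, input weights `Win`, sparse reservoir
`Wres`):

    R(t) = (1 - a) R(t-1) + a tanh(Win in(t) + Wres R(t-1))

and linear readouts per head on the concatenation `[R(t); in(t)]`. The
defaults follow the exemplar configuration: `a = 0.5`, reservoir sparsity
0.5, spectral radius 0.95 (rescaled exactly at initialisation), and a
desk-scale reservoir of `N = 1000` neurons — larger sizes, including the
15,000 of the full-scale configuration, are accepted through the
configuration but are not the default because the reference material is
internally inconsistent about the deployed size and the desk-scale size
decodes the synthetic tasks well within test budgets.

Three heads exist: `state` (one-hot targets, argmax decoding with
lowest-index tie-break), `trajectory` (raw 3D coordinates per hand, pure
regression — no argmax), and `satisfaction` (2-class one-hot, argmax).
One-hot target encoding is our choice; the source material does not state
the encoding.

### Online learning

* **RLS** (`rlsUpdate()`): textbook recursive least squares with
  forgetting factor 1 and `P0 = I / epsilon`. With these settings the
  online solution equals batch ridge regression with penalty `epsilon`, a
  property the tests verify to 1e-6. Two defaults differ deliberately
  from a naive configuration, both measured on the synthetic runner task:
  `epsilon = 10` (a ~1030-dimensional readout trained on ~1800 windows
  under-regularises at small `epsilon`: held-out balanced accuracy rose
  from 0.89 to 0.95 when `epsilon` went from 0.01 to 10), and ESN inputs
  are the z-scored spike rates with `inputScale = 0.1` (keeping reservoir
  pre-activations in the quasi-linear range of tanh, which lets the
  readout exploit reservoir memory instead of fighting saturation).
* **Reinforcement** (`rlUpdate()`): the satisfaction-gated rule
  `E <- delta E + (1 - delta) out (x)'` and
  `Wout <- Wout - alpha (1 - satisfaction) E`, applied once per flagged
  window to the state head. The trace product "[R in] out" is realised as
  the outer product `out (x)'` so the trace matches `Wout`'s shape — the
  only dimensionally consistent reading. With satisfaction = 1 the rule
  provably never changes a prediction (the trace still accumulates), and
  the tests check a 500-window run is bit-identical to one with the rule
  disabled.

### Update flags

Each window carries three flags: `reinforcement` (apply `rlUpdate` to the
state head, using the ground-truth satisfaction label when present and
the decoded one otherwise), `supervised` (RLS on the state head, and on
the trajectory head when the task has one), and `satisfaction` (RLS on
the satisfaction head). The binding of flags to operations is
configurable since the flag semantics are stated only loosely in the
source material.

## Voting

Per window, the plurality label among the bank members wins if its
supporter count reaches the threshold; otherwise — and on plurality ties —
the fallback label (typically idle) is returned. `selectVotingThreshold()`
picks the threshold maximising the balanced accuracy of the voted decision
on validation data, ties toward the smaller threshold. The "chosen" member
set {10, 30, 50, 70, 100, 110} Hz is the package default for
six-member voting. Voting operates per window; a session-level variant
would be a trivial reduction but is not implemented.

## The synthetic generator

`generateSession()` produces: 1/f (pink) background noise per channel
(default SD 20 µV, mimicking the broadband cortical spectrum);
state-gated carrier oscillations (default 30 Hz, baseline amplitude 10 µV)
on a configurable channel subset defaulting to one quadrant of the grid,
so electrode selection matters; a Markov state sequence with configurable
mean dwell (default 20 windows ≈ 2 s, a realistic motor-bout duration);
smooth 3D trajectory targets active only while the matching hand state is
on; satisfaction labels correct by construction and flipped at a
configurable error rate; and per-task update flags. In the active state
the carrier amplitude is multiplied by `sqrt(1 + effectSize)`, so carrier
band *power* rises by exactly `1 + effectSize`; `effectSize = 0` yields a
null session in which the labels are independent of the signal — the
idle-state samples are then bit-identical between a null and a non-null
session generated from the same seed, which the tests exploit.

What the generator does *not* emulate: volume conduction and inter-channel
correlation structure, non-stationarities (electrode drift, impedance
changes, circadian effects), movement artefacts, and the true spatial
topography of motor cortex. Passing tests on synthetic sessions therefore
demonstrate that the chain can extract a known spectral signature under
realistic noise, not that it reaches any particular accuracy on patient
recordings.

## Numerical choices and degenerate inputs

* Spike times are recorded at integration-step resolution; the closed-form
  LIF period is reproduced within 1% at `dt = 0.01 ms`, and halving `dt`
  changes reference spike counts by under 2%.
* The reservoir spectral radius is computed by dense eigendecomposition up
  to N = 1500 and by power iteration above.
* All-constant feature channels produce zero current (not an error); a
  zero `sd` in calibration statistics falls back to 1.
* Ties: argmax decoding and voting both break toward the
  lowest index / fallback deterministically.
* EDF output quantises to 16 bits over each channel's observed range and
  pads the tail to a whole number of records; physical min/max are written
  to the header exactly as they will be re-parsed, so round-trips are
  within one quantisation step.
* Randomness: every build (network wiring, reservoir, generator) takes an
  explicit integer seed; identical seeds give byte-identical objects, and
  decoding itself draws no random numbers.

## Scale of the shipped analyses

The held-out recovery analysis in the tests and the acceptance script uses
5-minute, 32-channel runner sessions (~2980 windows), a ~100-neuron SNN
and a 1000-neuron reservoir — sizes chosen so a full train/decode cycle
takes well under two minutes on one CPU while leaving the decoder
over-parameterised relative to the task. A single null session's held-out
segment holds only ~60 independent state bouts, so one draw of the
chance-level balanced accuracy has a standard deviation near 0.04; the
chance-level check therefore averages four independently generated null
sessions rather than widening its acceptance band.

## Known limitations

* Delta-current synapses and a uniform conduction delay; no
  conductance-based synapses or distance-dependent delays.
* The reinforcement rule is applied once per flagged window; repeated
  application per dissatisfaction episode is not implemented.
* The EDF codec covers continuous equal-rate signals (EDF and the
  continuous EDF+ subset) — enough for ECoG sessions, not a general
  biosignal archive reader.
* Checkerboard electrode selection assumes the pattern starts at the
  grid's first cell; the true implant pattern phase is unknown.
* No streaming transport: "pseudo-online" reads files and emits one CSV
  row per window, matching the reference workflow.
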