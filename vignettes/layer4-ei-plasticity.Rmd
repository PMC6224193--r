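---
title: "Opposing E-I ratio shifts in layer 4: models, quantification rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Opposing E-I ratio shifts in layer 4: models, quantification rules, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(l4ei)
```

## The scientific question

Closing one eye for two to three days depresses visually evoked responses in
layer 4 of monocular primary visual cortex. The classical explanation is
long-term depression of thalamocortical synapses onto pyramidal neurons. The
circuit picture this package implements is different: feedforward
(thalamocortical) drive is depressed onto *both* pyramidal neurons and PV+
interneurons, but more strongly onto the interneurons — so the feedforward
E-I ratio actually shifts toward excitation — while the *feedback* circuit
shifts toward inhibition because recurrent excitatory synapses onto
interneurons are potentiated. Whether circuit activity then rises or falls is
not answerable by inspection: two opposing pressures act at once, and a
spiking network model is needed to integrate them. `l4ei` provides (i) the
quantification rules that turn voltage-clamp recordings into the measured
ratios, (ii) the arithmetic that converts those ratios into synaptic scaling
factors, and (iii) the network model that evaluates their joint effect.

## The network model

Each of `N = 5000` neurons (`NE = 4000` excitatory, `NI = 1000` inhibitory)
is a conductance-based leaky integrate-and-fire unit,

$$C \frac{dV}{dt} = -g_L (V - V_L) - g_{exc}(t)(V - V_{exc}) - g_{inh}(t)(V - V_{inh}),$$

with `C = 200 pF`, `gL = 10 nS`, `VL = -70 mV`, `Vexc = 0 mV`,
`Vinh = -85 mV`, threshold `-50 mV`. A presynaptic spike increments the
postsynaptic conductance by the pathway's peak conductance, which then decays
exponentially with `tau_syn = 5 ms`. Every cell receives exactly 400
excitatory and 100 inhibitory recurrent connections (uniform, without
replacement, no autapses); the fixed in-degree is the binding wiring rule and
the 10% connection probability of the parameter table is its consequence,
not a Bernoulli rule. Recurrent weights are `j = 0.3 nS` (excitatory) and
`g_rc * j = 2.4 nS` (inhibitory). External drive is thalamic
(100 independent Poisson trains at 8 Hz, weight `js = 0.5 nS` onto
excitatory cells and `g_fw * js = 0.625 nS` onto inhibitory cells) plus
background (100 trains at 14.2 Hz, weight `js` onto both cell types). Because
all trains onto a neuron share one weight, each source is collapsed into a
single compound Poisson process per neuron — distributionally identical and
much faster.

### Scenario factors

The measured plasticity enters as three multiplicative factors on peak
conductances: depression of thalamic drive onto excitatory cells
(`delta_E = 0.9`), depression onto inhibitory cells (`delta_I`), and
potentiation of recurrent excitation onto inhibition (`pi`). `delta_I` is not
measured directly: the deprived/control shift of the pyramidal/PV EPSC charge
ratio equals `delta_E / delta_I` because both cell types share the same
thalamic afferents, so `derive_delta_i(0.9, ...)` with a shift of 1.5 gives
`delta_I = 0.6`. Similarly the intracortical E-I ratio shift, attributed
entirely to E-to-I potentiation (PV-to-pyramidal synapses are unchanged),
gives `pi`. Note that the printed group means of the intracortical ratios
(0.091 and 0.066) give `derive_pi() = 1.38`, while the conventional rounded
value is 1.5; simulations here default to 1.5, and both values are
reportable. The TC scenario applies `(delta_E, delta_I)` to thalamic drive;
TC+IC additionally applies `pi` to recurrent E-to-I weights. Background drive
and recurrent inhibition are never scaled.

### Decisions the measurements do not constrain

Several integration details are not fixed by the measured parameters. They
are explicit arguments, recorded in every result file:

* **Reset and refractoriness.** `Vreset = VL = -70 mV`, `t_ref = 2 ms` —
  the common convention for sparse random networks of this family.
* **Recurrent delay.** 1 ms uniform on recurrent synapses, none on external
  drive; a nonzero delay avoids same-step feedback artifacts. The integrator
  enforces a minimum effective delay of one step.
* **Integration scheme.** Exponential-Euler with `dt = 0.1 ms`: conductances
  decay exactly between steps; the voltage update uses the step-midpoint
  conductance, which makes population rates second-order accurate in the
  synaptic time course. Halving `dt` moves population rates by about 1%
  (checked in the test suite).
* **Initial conditions.** `V(0)` uniform on `[VL, Vtheta)` per neuron from
  the simulation seed (or exactly `VL` with `init = "rest"`).
* **Units.** `mV, ms, nS, pA, pF` throughout — internally consistent
  (`nS * mV = pA`, `pF * mV / ms = pA`), so no hidden conversion factors.

### Validation oracles

The integrator is checked against independent references rather than against
itself: (i) the closed-form ISI of a single neuron under a clamped 10 nS
excitatory conductance (agreement within 1%); (ii) the mean free membrane
potential of an unconnected population under full drive, predicted from the
mean conductance `j_s * tau_syn * total rate = 5.55 nS` (within 1 mV);
(iii) a plain-R forward-Euler reference integrator run on an identical
external input realization of a 50-neuron recurrent network (population
rates within 5%); (iv) a `dt`-halving convergence check. The closed-form
rheobase `gL (Vtheta - VL) = 200 pA` and input resistance `1/gL = 100 MΩ`
anchor the FI analysis.

## The three in-silico experiments

**Paired-seed condition comparison.** BL, TC and TC+IC share one
connectivity and one input realization, so rate differences reflect only the
weight changes. With the measured factors `(0.9, 0.6, 1.5)`, TC raises both
population rates (net disinhibition) and TC+IC lowers both below baseline —
the feedback shift dominates.

**Monte-Carlo robustness sweep.** `(j, g_rc, R_LGN, R_BKG)` are drawn
independently and uniformly from the standard ranges (0.1-0.4 nS, 7-10,
5-15 Hz, 5-15 Hz); networks whose baseline rates match user-supplied target
rates within ±10% (both populations jointly, configurable) are kept and
subjected to TC and TC+IC. The reference targets are deliberately not
defaulted in the package: they represent in vivo firing rates that are an
experimental input, not a model constant. The test suite uses E = 5 Hz,
I = 12 Hz — typical in vivo rates for layer 4 regular-spiking and
fast-spiking cells — chosen once, before the sweep, as the package's own
study condition. The shipped analysis scale is 500 draws of a 1000-neuron
network simulated for 3 s with a 0.5 s transient; this is a documented
scaled-down design relative to a full 100,000 x 9 s campaign, which the same
function reproduces given the time. When `N` is reduced, the per-neuron
in-degrees are kept at the model's fixed 400/100 rather than scaled
proportionally: the in-degree is the binding wiring rule, and preserving it
preserves each neuron's input statistics — proportional scaling weakens
recurrence relative to external drive and changes which effects can
dominate. A consequence worth stating plainly: whether the TC+IC decrease
holds across *all* rate-matched networks depends on where the (user-chosen)
targets place the matched networks in parameter space. Targets that are
matched by weakly coupled networks select operating points where external
drive dominates recurrence, and there the feedback potentiation — whose
impact scales with the recurrent weight times the excitatory rate — cannot
outweigh the thalamic disinhibition, leaving TC+IC slightly above baseline
for the excitatory population.

**The (ρEI, π) grid.** `delta_E` is fixed at 0.9; `delta_I = delta_E / ρEI`
varies the thalamocortical shift, and `pi` the feedback shift, both over
`[1, 1.5]`. All cells share one connectivity and input realization. The grid
is normalized to its own `(1, 1)` cell — uniform 0.9 thalamic depression
with no feedback change — because with `delta_E` fixed the `(1, 1)`
configuration *is* the grid's baseline: this makes the `(1, 1)` cell exactly
100% by construction, and the `(1.5, 1.5)` cell reproduces the paired
pipeline's TC+IC simulation bit for bit under the same master seed. Across
the grid, excitatory rates fall along the `pi` axis much faster than they
rise along the `ρEI` axis: the feedback potentiation dominates.

## Synthetic recordings and quantification rules

No raw recordings ship with the package; generators produce every paradigm
with exact ground truth, which is what makes the quantification rules
testable. The event kernel is a peak-normalized difference of exponentials
`(1 - e^{-t/τ_r}) e^{-t/τ_d}` (the shape is a modelling choice — amplitudes
are then literal peak amplitudes); amplitudes are lognormal (strictly
positive and right-skewed, like empirical mEPSC amplitude distributions);
sample noise is i.i.d. Gaussian at 10 kHz. The generators emulate stationary
Poisson event streams, linear charge-intensity scaling, multiplicative LTD
noise and binomial minimal-stimulation successes; they do not emulate
electrode artifacts, series-resistance errors, filtered (colored) noise or
nonstationary drift — so passing tests certify the analysis rules, not
robustness to every pathology of real recordings.

Quantification conventions, where the convention itself was open:

* **Event detection** thresholds the smoothed (1 ms boxcar),
  baseline-subtracted trace at 3.5 robust SDs (median filter baseline,
  250 ms window, so slow events and drift do not corrupt it; a relative
  floor handles noiseless traces). Amplitude and the interpolated 20-80%
  rise time are measured on the raw trace; the peak is read as a ±0.2 ms
  average. A candidate onset within one rise time of the previous peak is
  merged — a deterministic stand-in for what is, in practice, manual
  curation of overlapping events. Sub-threshold candidates are *detected*
  but flagged `included = FALSE` by the 5 pA / 3 ms criteria, mirroring how
  inclusion filters are applied in practice.
* **Charge** is the absolute trapezoidal integral of the baseline-subtracted
  current over a 100 ms post-stimulus window (10 ms pre-stimulus baseline);
  windows are half-open so response and baseline never share a sample.
* **Decay constants** come from log-linear least squares over a 10 ms
  post-peak window; non-decaying or truncated segments are flagged rather
  than fitted.
* **Minimal-stimulation successes** exceed 3 baseline-noise SDs in a
  2-20 ms post-stimulus window, both measured at the same 1 ms smoothing
  bandwidth. Because the peak is a maximum over the window, a small
  fraction of pure-noise trials can cross; `threshold_k` is configurable
  where a conservative classification matters.
* **Degenerate inputs** error with typed conditions (`l4ei_invalid_window`,
  `l4ei_all_excluded`, `l4ei_estimate_undefined`, ...) naming the violated
  rule rather than returning silent NAs; an FI protocol with no spiking step
  returns the curve and warns that rheobase is undefined.

## Problem sizes and reproducibility

The default test-suite scales are: full-size (N = 5000) paired comparisons
at 3 s per scenario with a 0.5 s transient across ten seed replicates;
500-draw sweeps and 4x4 grids at N = 1000 for 3 s. These sizes give stable
steady-state rate estimates (tens of thousands of spikes per estimate) while
keeping the whole suite comfortably runnable on a laptop; the full 9 s
durations of the shipped configuration behave identically.

All randomness flows from explicit seeds: a master seed derives
per-stage substreams (`derive_seed(seed, "connectivity")`,
`derive_seed(seed, "input")`, per-network streams in sweeps) so that paired
scenarios share realizations exactly, identical calls are bit-identical, and
any result file — which embeds its seed, configuration fingerprint and
decision parameters — can be regenerated.

## Known limitations

* Factors are applied statically; there is no plasticity during simulation.
* One excitatory and one inhibitory population; no spatial structure,
  synaptic depression/facilitation, or cell-type diversity beyond E/I.
* The event detector is tuned for quantal events at 10 kHz with rise times
  well under the decay; heavily overlapping bursts are merged, not
  deconvolved.
* `derive_pi` attributes the whole intracortical shift to E-to-I
  potentiation; alternative attributions (e.g. changes in other interneuron
  classes) are outside the model.
* Uncertainty is not propagated through the factor arithmetic: factors are
  point values, as in the underlying analysis.
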