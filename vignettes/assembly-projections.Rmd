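---
title: "Assembly projections: model, protocols, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly projections: model, protocols, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`apnet` simulates how abstract structural categories (such as the agent and
patient roles in a sentence) can be dynamically bound to content
representations in generic networks of spiking neurons.  The mechanism is
the *assembly projection*: when a structural subnetwork (a "neural space")
is disinhibited while a content assembly is active, fast Hebbian plasticity
carves out a sparse assembly in the neural space that is bidirectionally
coupled to the content assembly.  Disinhibition plus a slowly decaying
per-neuron excitability trace then supports a small repertoire of
operations — CREATE, LOAD, RECALL, COPY and COMPARE — on these bindings.

This vignette documents the model equations, the operation protocols, the
parameters that matter (with units and defaults), and the numerical and
design choices behind the implementation.  Nothing here states an empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The neuron model

All network neurons are stochastic point neurons.  Neuron $i$ fires in a
time step of length $\Delta t$ with probability $1 - e^{-\rho_i \Delta t}$,
where the hazard is

$$\rho_i = \max\!\big(0,\; c_1 V_i' + c_2 (e^{c_3 V_i'} - 1)\big),$$

with $V_i' = V_i + b_i$ the effective membrane potential.  Excitatory
neurons use the exponential branch ($c_1 = 0$, $c_2 = 1000$ Hz,
$c_3 = 1/\mathrm{mV}$), inhibitory neurons the linear branch
($c_1 = 10$ Hz/mV, $c_2 = 0$).  The membrane integrates with the exact
exponential-Euler update

$$V_i(t) = e^{-\Delta t/\tau_m} V_i(t - \Delta t) +
  (1 - e^{-\Delta t/\tau_m})\, R_m (I_{syn} + I_{inh} + I_e),$$

with $\tau_m = 10$ ms, $R_m = 0.5\ \mathrm{M\Omega}$, and a bias current
$I_e = 0.2$ nA for excitatory neurons only.  After a spike the potential
resets to zero and the neuron is refractory for a per-neuron duration drawn
once at construction from a Gamma distribution (shape 4, scale 3.5 ms, mean
14 ms).  During the refractory period the neuron neither integrates nor
spikes; arriving inputs are discarded for the voltage but remain visible to
plasticity (a presynaptic event is a fact regardless of the target's
state).  The alternative reading of the Gamma parameter as the *mean*
(3.5 ms) is available as `model_params(refr_mode = "mean")`; under it the
inhibitory pool's firing is no longer rate-limited, the balance tips
strongly toward inhibition, and recall fails to ignite — which is why the
scale reading is the default.

Excitatory neurons in neural spaces carry an excitability trace $b_i$: each
spike increments it by $q_{sfa} = 0.02$ mV up to a cap of 0.5 mV, and it
decays with $\tau_{sfa} = 5$ s.  This trace is the model's short-term
memory of "which assembly was active most recently" and is what RECALL
exploits.  Content-space and inhibitory neurons have $q_{sfa} = 0$.

### The inhibitory lock

Every space can be *locked*: all of its neurons then receive a strong
constant current $I_{inh} = -4$ nA, pinning the excitatory fixed point at
$R_m(I_e + I_{inh}) = -1.9$ mV, where the exponential hazard is clipped to
zero.  Locking a space silences it and (for neural spaces) closes the
plasticity gates of every synapse group touching it.  Neural spaces are
locked by default; the content space is disinhibited by default and locked
only transiently (the first 50 ms of every recall).

### Synaptic unit convention

Synapses are delta synapses: a presynaptic spike through an edge of
tabulated weight $w$ causes an instantaneous membrane-potential jump at the
target after the edge's conduction delay.  The weight tables do not come
with a usable current-times-resistance conversion (taken literally,
pA × MΩ yields sub-microvolt deflections that cannot drive the reported
dynamics), so the package fixes the conversion as two calibrated scales:

* static within-space E/I synapses: `w_unit_static_mV = 0.022` mV per unit,
* plastic excitatory synapses: `w_unit_plastic_mV = 0.25` mV per unit,
* comparison-readout synapses: 1 mV per unit (times the release efficacy).

Both network scales were fixed once, by requiring the constructed network
to reproduce the model's stated operating points — content assemblies of
several dozen neurons out of 1000 driven above 50 Hz by their patterns,
recurrent-weight saturation within and silence between assemblies, a
functioning inhibitory lock, and a functioning RECALL — and are not
otherwise tuned.  A single shared scale cannot do this: the static E/I
couplings must be roughly an order of magnitude weaker per tabulated unit
than the plastic couplings, otherwise the inhibitory feedback either
extinguishes all excitatory activity or fails to separate assemblies.

## Plasticity

All synapses between excitatory neurons are plastic; E/I synapses are
static.  A pairing of a presynaptic and a postsynaptic spike with lag
$\Delta t = t_{post} - t_{pre}$ contributes

$$\Delta w(\Delta t) = \begin{cases}
 \eta\,(e^{-|\Delta t|/\tau_+} - A_-) & \Delta t \ge 0\\
 \eta\,\alpha\,(e^{-|\Delta t|/\tau_-} - A_-) & \Delta t < 0,
\end{cases}$$

with per-connection-type parameters (`model_params()$plastic`) and hard
clipping of every weight to $[0, w_{max}]$ after every update.

**Pairing scheme.**  The rule's constant $-A_-$ offset makes the pairing
scheme part of the model, not a numerical detail.  The package applies the
$\Delta t \ge 0$ branch *once per postsynaptic spike*, accumulating the
exponential term over all presynaptic spikes within the pairing window
($10 \max(\tau_+, \tau_-)$) while counting the offset once:

$$\Delta w_{post} = \eta\,\Big(\sum_{t_{pre}} e^{-(t_{post}-t_{pre})/\tau_+}
  \;-\; A_-\Big).$$

In expectation this compares the presynaptic activity trace
$r_{pre}\,\tau_+$ against $A_-$, so each connection type has a presynaptic
*rate threshold* $A_-/\tau_+$ above which co-activation potentiates and
below which an active postsynaptic neuron actively depresses the edge.
With the tabulated parameters these thresholds are 16 Hz (input to
content), 23.5 Hz (feedback), 20 Hz (content recurrent), 13.3 Hz
(feedforward) and 14 Hz (neural-space recurrent) — all lying between the
idle input rate (12.5 Hz) and assembly firing rates (>50 Hz), which is
what makes induction selective and drives cross-assembly weights toward
zero.  Two alternatives were examined and rejected: counting the offset
per pre/post spike pairing accumulates a depression that grows without
bound with the presynaptic rate (all weights collapse), and any symmetric
nearest-neighbor scheme makes co-active pairs net-depress because the
depression window $\tau_-$ is wider than $\tau_+$ at equal offset.

The $\Delta t < 0$ branch is applied per presynaptic spike to the most
recent postsynaptic spike that had no presynaptic spike within the window
before it (each postsynaptic spike is claimed at most once), which keeps
$\alpha$ and $\tau_-$ meaningful without double-counting.  Pairings use
spike emission times; conduction delays affect delivery only.  Connection
types without a depression branch have $\alpha = 0$.

**Gating.**  Plasticity of every synapse group with an endpoint in a
neural space is enabled only while that space is disinhibited.  After
assembly induction, the input-to-content and content recurrent groups are
frozen permanently.  Content-space locking does not gate plasticity.

**Short-term depression.**  The comparison readout receives depressing
synapses governed by the standard two-variable release/recovery recursion
(resources $x$, utilization $u$; `tm_params()`: $U = 0.25$,
$\tau_{rec} = 700$ ms, $\tau_{fac} = 20$ ms, weight 50).  These values are
literature-derived stand-ins for a strongly depressing facilitating
synapse type; the comparison verdict threshold is calibrated on a grid,
not hard-coded, so moderate changes to them shift the threshold rather
than break the operation.

## Network architecture

`build_network()` constructs an input population X (200 Poisson
generators), a content space C (1000 excitatory + 250 inhibitory neurons)
and any number of neural spaces (2000 + 500 each).  Excitatory pools are
recurrently connected with probability 0.1 (no self-connections); E→I,
I→E and I→I connections use the tabulated probabilities and static
weights; X projects all-to-all onto C's excitatory pool; C and each neural
space are bidirectionally and independently connected with probability
0.1.  Initial weights and conduction delays are uniform within their
tabulated bounds.  Wiring seeds are derived per component from the master
seed, so adding a neural space never changes the content-space
realization, and neural spaces can be re-instantiated over a fixed trained
content space.

## Stimuli

Each input pattern activates 25 of the 200 input neurons at 100 Hz; the
rest fire at 0.1 Hz.  Up to eight patterns use disjoint active sets;
beyond that (capacity sweeps) independent random 25-subsets are drawn and
overlap is permitted.  Between presentations all input neurons idle at
12.5 Hz, which keeps the mean population input rate approximately constant
(25·100 + 175·0.1 ≈ 200·12.5).  A reduced-rate preset (60 Hz active / 1 Hz
background) is provided for robustness checks.

## Operation protocols

* **Induction** — 200 pattern presentations drawn i.i.d. (200 ms pattern +
  200 ms idle), content space disinhibited, neural spaces locked.
  Afterwards input and content recurrent plasticity is frozen, and each
  pattern is probed once; neurons firing above 50 Hz in the probe's second
  half form that pattern's assembly.  The linear content readout is
  trained on the probe responses.
* **CREATE** — one pattern presented for 1000 ms while the target neural
  space is disinhibited.  `establish_projections()` performs three CREATE
  passes per pattern (the later passes saturate the feedforward/feedback
  coupling) with 15-s fully locked rests in between.
* **LOAD** — a 200-ms CREATE against already-established projections;
  refreshes the projection's excitability trace.
* **RECALL** — the neural space is disinhibited for 200 ms with idle
  input; the content space stays locked for the first 50 ms.  The
  projection selected by its excitability trace ignites first and then
  reactivates its content assembly through the feedback synapses.  The
  recalled set is read from second-half firing rates (>50 Hz), and the
  readout error is the fraction of misclassified 1-ms filtered samples in
  the window from 50 ms to 200 ms after recall onset.
* **COPY** — recall from the source space with a 100-ms additional
  disinhibition of the target space, which imprints the same content
  there; verified by a later recall from the target.
* **COMPARE** — both spaces are loaded (200 ms each + 50 ms idle), then
  recalled in sequence (200 ms each, content locked for the first 50 ms of
  each).  The readout population (50 leaky integrate-and-fire neurons,
  resting −60 mV, threshold −20 mV, $\tau_m$ 20 ms, 5-ms refractory clamp
  at rest) receives sparse depressing synapses from the content space; a
  repeated content finds its synapses still depressed, so near-absent
  second-phase activity means "same".  The verdict threshold is the
  log-scale midpoint between the two phase-2 activity groups of a
  calibration grid.

**Inter-operation timing.**  The excitability trace decays over seconds,
so consecutive operations interact: a CREATE performed seconds after
another would re-ignite the previous winner and merge projections.  The
shipped protocol therefore inserts rest periods of 15 s between CREATEs
and 20 s between recall trials in which every space (content space
included) is locked, resetting all recurrent activity.  The load–recall
delay within a trial is 5 s, during which the neural spaces are locked
(no memory in recurrent activity) while the content space stays
disinhibited under idle input.

## What the synthetic data emulate — and what they do not

All inputs are synthetic rate patterns; the generator's defaults *are* the
study conditions (25-of-200 at 100 Hz, idle 12.5 Hz, five patterns, 200
presentations).  Passing tests therefore show that the binding mechanism
works for sparse, rate-coded, essentially non-overlapping content tokens
presented under a controlled disinhibition schedule.  They do not show
robustness to naturalistic stimulus statistics, overlapping concept codes,
sensory preprocessing, or unsupervised disinhibition control, none of
which the model attempts.

## Scaled suite sizes

The full-scale reproduction (5 content instances × 10 neural-space seeds,
250 recall trials; 50 copies; 100 robustness samples) runs for hours.  The
default desk profiles used in the test suite and the acceptance script
keep every duration and parameter at full scale and reduce only
multiplicities: one content instance, five patterns, one neural-space
seed for the reduced-induction recall suite, three copy trials, a 2 × 2
comparison grid, and a single-sample robustness spot check.  The suite
runner profiles (`default_config()`) provide larger desk and full-scale
multiplicities for offline runs.  The methods are identical at every
scale.

## Known limitations

* The spontaneous firing rate of the disinhibited content space at the
  calibrated operating point (~3.5 Hz under idle input after induction) is
  lower than the model's nominal 5.5 Hz operating point; configurations
  that raise the spontaneous rate to 5.5 Hz weaken the recall operation
  along every available dial.  The spontaneous rate is reported as
  computed, not adjusted.
* Content assemblies at the calibrated operating point come out at roughly
  80–115 neurons, somewhat above the nominal 50–90 band; shrinking them
  (more inhibition) degrades recall completion.
* RECALL sits close to the similarity criterion's 80% retention boundary:
  the readout decodes the recalled content with essentially zero error,
  but the fraction of reference-assembly neurons driven above the strict
  50 Hz mark in the scoring window hovers around 0.75–0.85, so individual
  trials fall on either side of the criterion.  Stronger recurrent
  coupling completes the assembly but destabilizes the inhibitory lock of
  the other, locked spaces in multi-space networks; the shipped operating
  point keeps every operation functional instead.
* During operations that drive the content space at full assembly rate,
  the locked spaces' matching projections receive enough feedforward
  drive to leak through the lock.  The leak is content-consistent (it
  refreshes the excitability trace of the very assembly being processed)
  and is contained by each space's inhibitory pool at the shipped
  coupling scales.
* The 0.1-ms time step quantizes spike times and delays; delays are
  rounded to the grid.
* Spike delivery uses the synaptic weight at emission time (not delivery
  time); at 1–10 ms delays and the given learning rates the difference is
  far below one weight-clipping quantum per spike.
* In-flight spikes and pairing histories are continuous across the phases
  of one operation, but not across separate operations; operations are
  separated by rest periods much longer than any delay or pairing window,
  so nothing observable is lost.
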