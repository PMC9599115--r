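---
title: "Models and methods behind spinecap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spinecap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`spinecap` asks how spatiotemporal patterns of in-vivo-like synaptic input
control calcium-based synaptic plasticity in a striatal spiny projection
neuron (SPN), at a scale that runs on a single CPU in minutes. This
vignette documents the models, the parameters that matter, the numerical
choices, and the design decisions taken where the design was genuinely
open — in the package's own words, so that a user can judge what the
simulations do and do not show.

## The plasticity rule

The core object is a weight-update rule driven purely by spine calcium
concentration, with two amplitude and two duration thresholds. Depression
engages while spine calcium has remained at or above T_AD = 0.33 µM (but
below the LTP threshold) for longer than 28 ms; potentiation engages while
calcium has remained at or above T_AP = 0.53 µM for longer than 3.3 ms.
While engaged, the weight moves every step by a capped, calcium-
proportional gain with soft bounds, so `w` is confined to [0, 2] and
asymptotes at the bounds; a synapse sitting exactly at a bound no longer
moves (the soft-bound factor is zero there).

Conventions that the rule's published form leaves open, fixed here:

* **Amplitude comparisons are closed (`>=`)**, with a 1e-9 µM guard against
  floating-point ties. A plateau at exactly the printed threshold therefore
  engages the branch — with vanishing gain, since the gain is proportional
  to the threshold excess. This makes threshold-recovery scans on a 0.01 µM
  grid land exactly on the printed values instead of one grid step above,
  and is inconsequential for mechanistic traces, which never sit at a
  threshold with positive measure. **Duration criteria are strict (`>`)**,
  reading "for longer than": a 28 ms pulse at 0.40 µM does nothing, a 29 ms
  pulse depresses.
* **Excursion timers are continuous**, resetting whenever calcium drops
  below the corresponding amplitude threshold; they are not cumulative
  within a trial.
* **Gains are per millisecond** and multiplied by the trace step, so
  trajectories are step-size invariant (verified to < 1 % under step
  halving on smooth traces). The gain magnitudes are not constrained by the
  thresholds themselves; the defaults (γ_P = 0.0044 /ms/µM, cap
  γ_Pmax = 0.0066 /ms; γ_D = 0.002, γ_Dmax = 0.003) are set so that a
  100 ms plateau at 1.0 µM moves `w` from 1 by about +0.1 — a visible but
  far-from-saturating change per strong trial-level event.
* `detect_plasticity_events()` reports the onsets of *rule engagement*
  (both criteria met). At any amplitude strictly inside a branch this
  coincides with the onset of nonzero weight change; at the exact branch
  boundary engagement is the well-defined limit of "produces a change", and
  is what the threshold scans use.

## The reduced neuron

The electrical model deliberately replaces a full multi-channel,
morphologically reconstructed SPN with the smallest model that preserves
what the plasticity question needs: a dendritic tree with a
proximal/distal axis, spines as electrical and biochemical compartments,
synaptic conductances with NMDA voltage dependence, somatic spiking with
passive back-propagation, and a voltage-gated calcium source.

* **Morphology**: 4 primary dendrites, each two 16 µm segments and then two
  secondary branches of six 16 µm segments (soma-to-tip path 128 µm,
  ~900 µm dendrite total), diameters tapering 2.2 → 0.8 µm. Passive
  constants RM = 6.02 Ω·m², CM = 0.011 F/m², RA = 1.3 Ω·m, resting
  potential −85 mV.
* **Spines** (head 0.5×0.5 µm, neck 0.12×0.5 µm) are separate cable nodes
  coupled through the neck resistance (~57 MΩ at these dimensions). At this
  neck resistance spine heads are largely electrically slaved to their
  shaft; spine-specific calcium comes from spine-specific NMDA input, not
  from local electrical compartmentalization.
* **Synapses** are normalized dual exponentials (peak conductance =
  `gmax × weight`). AMPA 0.3 nS (τ 1.1/5.75 ms), NMDA 2.3 nS
  (τ 2.2/115 ms) with the standard single-exponential magnesium block
  (1 mM Mg, `1/(1 + [Mg]/3.57 · exp(−V/16.13))`), GABA-A 1.9 nS
  (τ 0.5/10 ms, E = −75 mV), four GABA synapses per dendritic compartment
  driven at 12 Hz within 80 µm of the soma and 8 Hz beyond.
* **Somatic spiking** is a minimal two-conductance mechanism (instantaneous
  Boltzmann fast inward, first-order delayed outward), tuned only to
  produce spikes from rest near −50 mV threshold with repolarization — it
  stands in for the full channel complement whose optimization is out of
  scope here.
* **The lumped high-voltage-activated calcium conductance** (1.6 nS per
  spine, plus a small dendritic density) feeds the calcium model only; its
  current is not added back to the membrane equation. It supplies the
  depolarization-gated, synapse-unspecific calcium component (back-
  propagating spikes, local plateaus) that cooperates with NMDA influx.

Synaptic and channel magnitudes are model inputs, not outputs: they were
chosen so that the default 50-train trial drives the soma at an
in-vivo-like rate (roughly 1–15 Hz during the trial), spine calcium peaks
span ~0.1–2 µM with the most active synapses crossing the LTP threshold,
and both depression and potentiation occur in a minority of synapses per
trial. This operating point is verified by the test suite rather than
assumed.

## Calcium dynamics

Each dendritic compartment that hosts spines carries concentric radial
shells (outermost submembrane shell 0.1 µm thick); each spine carries one
head slab and two neck slabs coupled axially into the submembrane shell.
Influx (a fixed 30 % of NMDA current as calcium charge, plus the lumped
VGCC current) enters the spine head or the submembrane shell; buffers bind
by mass action; PMCA (all membrane) and NCX (spines only) extrude with
Michaelis–Menten kinetics, balanced at rest by a constant leak so the
resting state (50 nM free calcium, buffers at binding equilibrium) is an
exact fixed point.

Default buffer kinetics are representative literature values: calbindin
160 µM sites (kon 0.028 /µM/ms, koff 0.0196 /ms, D 0.028 µm²/ms),
calmodulin N-lobe 20 µM (0.77, 16, 0.066) and C-lobe 20 µM (0.025,
0.00925, 0.066), immobile buffer 160 µM (0.247, 0.524). Pump maxima
0.035 ×10⁻²¹ mol/µm²/ms with Km 0.3 µM (PMCA) and 1.0 µM (NCX). The
published source constrains these only indirectly (through imaging data we
do not have), so they are exposed in `calcium_params()` and were fixed
once to give synaptically driven spine transients of order 0.1–1 µM.

Numerics, per integration step (default 0.025 ms, shared with the voltage
solver): influx is interleaved with a **semi-implicit mass-action update**
(implicit in the bound fraction, sub-stepped 8×) — explicit kinetics are
unstable against the fast calmodulin N-lobe at large transients, and the
semi-implicit form is exactly calcium-conserving; diffusion uses **pairwise
exponential relaxation** of concentration differences (exact for an
isolated pair, mass-conserving, unconditionally stable on the stiff
spine-neck couplings); extrusion is explicit. With pumps and influx off,
total calcium is conserved to machine precision; halving the step changes
spine-head peaks by under 2 %. Negative concentrations abort the run with
a diagnostic naming the element and step.

## Synthetic inputs

The generator emulates the statistics of simultaneously recorded motor
cortex units feeding a striatal neuron during a trained behavior, without
reproducing any particular dataset:

* heterogeneous per-train rates (log-normal, median 4 Hz, log-SD 0.8), so
  a few trains carry many spikes and many carry few;
* one shared multiplicative latent profile (smoothed log-normal, SD 0.5,
  correlation time 100 ms), which induces within-trial correlations between
  trains — the feature that ISI shuffling destroys;
* a deterministic late-trial ramp (quadratic rise over the last 30 % of the
  trial to 2.5× baseline), emulating motor preparatory activity.

What it does **not** emulate: refractoriness and burst structure of real
units, cross-trial nonstationarity, behavioral covariates, or the
recording selection step of pooling similar behavioral trials. Passing
tests therefore show that the *mechanism* behaves as described under
controlled correlated drive, not that any specific cortical dataset would
produce the same numbers.

The variability surrogates follow the stated constraints exactly: jitter
draws from a normal distribution truncated to the trial window by inverse-
CDF sampling (count-preserving, reproducible, and converging to uniform as
σ → ∞); spike moving conserves the total spike count and draws target
trains proportionally to their pre-move spike counts (a single-train input
is rejected — no valid target); ISI shuffling anchors the first spike at
its original time and permutes subsequent intervals, preserving the ISI
multiset and the train span. Variability is always applied to the initial
trial, never compounded across repetitions. The experiment timeline places
a 1 s intertrial interval after every trial plus a 1 s lead-in, so the
default 10-trial experiment spans 21 s; this is one consistent reading of
the stated total duration, fixed here once.

## Cluster mappings

Spines are placed uniformly over eligible arc length (path distance
> 25 µm from the soma; 0.1/µm distributed, 0.75/µm on ~200 µm of distal
dendrite for clustered experiments — within the stated 0.75–2.75 range,
kept at the low end so 125 distinct mappings remain feasible at desk
scale). Cluster construction is greedy: anchors drawn uniformly over
remaining spines, members added in order of increasing path distance to
the anchor under the constraint that the maximum *pairwise* dendritic
distance stays within the cluster length; infeasible configurations fail
with an explicit error naming the constraint. All distances are tree
distances along the dendrite, never Euclidean, and the "19 nearest
neighbors" ordering is deterministic (path distance, ties by spine id).
The default cluster sweep pairs 5 configurations (1, 2, 5, 10, 20 spines
per cluster with lengths 5, 10, 20, 40, 80 µm) with 5 mapping seeds each —
25 single-trial simulations, a reduced analogue of a full crossed design.

## Pipeline staging

`simulate_experiment()` runs voltage, calcium and weights in one fused
fixed-step loop, but the stages are **open loop**: synaptic conductances
use the initial weights throughout an experiment, while weights accumulate
across trials from the calcium traces. This matches the package's module
contract (generate → map → voltage → calcium → weights → analyze) and
makes every stage independently testable against prescribed inputs; the
cost is that induced weight changes do not feed back into the electrical
drive within an experiment. For the single-trial cluster analyses this is
immaterial; for multi-trial experiments it means weight trajectories are
eligibility-style accumulations rather than closed-loop dynamics.

All randomness descends from one root seed with fixed per-stage offsets
(trains +1, spine placement +2, mapping +3, variability +4, inhibition
+5), recorded in the output manifest; re-running a configuration
reproduces every table bit-identically.

## Analysis choices

* Instantaneous firing rate: Gaussian kernel, σ = 50 ms, reflected at the
  trial edges so the rate integrates to the spike count (within 1 %); the
  method is a choice, logged with results, since only "instantaneous
  firing rate" is specified.
* Weight-change triggered average: 7 bins, symmetric about zero, with a
  dedicated near-zero bin of half-width 0.01 (0.5 % of the weight range)
  and outer edges from quantiles of |Δw|; edges are returned with every
  result. Empty bins are reported with count 0; an all-identical Δw input
  degenerates to a flagged single bin.
* Random forest: `ranger`, 500 trees, default depth, impurity importances
  normalized to sum to 1; 5 × 4 random 75/25 train/test splits by default.
  Post-hoc comparisons are Welch t-tests without multiplicity correction
  (matching the reporting style of the analyses this mirrors; noted in the
  output).
* Instantaneous weight-change events use the latest pre- and post-synaptic
  spikes *at or before* the event; events lacking the required spikes are
  flagged and excluded from the regressions that need them.

## Problem sizes and runtimes

The default experiments are sized for a single CPU: 50 excitatory trains
on ~80 spines (distributed) or ~150 spines (clustered), 10 trials of 1 s
for variability experiments (~1 min each), 25 single-trial simulations for
the cluster sweep (~2 min), random-forest comparisons on ~1250
synapse-trial rows (~1 min). These sizes are the package's default study
conditions; all scale up through configuration.

## Known limitations

* The somatic spike generator is minimal: no afterhyperpolarization
  complex, no inward rectification, no adaptation. Firing rates are tuned
  by synaptic balance rather than intrinsic currents, and the model sits
  closer to a knife edge between silence and sustained firing than a full
  SPN would.
* No calcium-dependent channel feedback (the reduced model omits the
  calcium-activated potassium and chloride channels), and the VGCC is one
  lumped conductance rather than six subtypes.
* Open-loop weight staging, as discussed above.
* Dendritic calcium is modeled only in compartments hosting spines, and
  dendritic axial calcium diffusion between compartments is not modeled
  (radial shells only, as specified for the dendrite).
* Clustered high-density inputs push the model toward potentiation
  dominance; depressing synapses remain a minority there, which is why the
  weight-change bins are quantile-based rather than fixed.
* Neuromodulation (dopamine gating of consolidation) is out of scope; the
  rule here is the induction/eligibility computation only.
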