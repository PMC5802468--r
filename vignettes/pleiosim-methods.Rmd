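---
title: "Models and methods behind pleiosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pleiosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pleiosim)
```

`pleiosim` asks one question end to end: when the same ion-channel or
calcium-transporter gene variant is expressed both in a cortical neuron
and in a cardiac pacemaker cell, do its effects on excitability point in
the same direction or in opposite directions?  The package supplies the
cell models, the variant algebra, the calibration that keeps variant
effects "subtle", the excitability protocols, the tissue-level
propagation models, and the cross-cell-type aggregation that answers the
question.  This vignette documents the science and the numerical choices;
the README shows the workflow.

## Cell models

### Why reduced models

The package ships three conductance-based models: a reduced two-compartment
layer-V pyramidal neuron (`neuron-reduced`) and two single-compartment
sinoatrial node cells (`san-mouse`, `san-rabbit`).  All three are written
as Hodgkin–Huxley-type systems: every gate has a Boltzmann steady-state
curve (half-activation voltage, slope factor) and a voltage-dependent time
constant with a tunable multiplier.  This parameterisation is what makes
the variant machinery possible — a functional-genomics observation such as
"activation shifted by −5 mV" or "conductance halved" maps directly onto
one named model parameter.

The neuron is deliberately reduced rather than morphologically detailed.
Its role in the analysis is *directional*: what matters is the sign of a
variant's effect on firing, not the absolute firing rate of a particular
reconstructed cell.  Reduced models make signs and monotonicity cheap to
establish and test; all neuron-side claims in the package are therefore
property-based (signs, monotonicity, ordering), never absolute rates.

The sinoatrial models are reduced reformulations with the classic nodal
current repertoire: two L-type Ca components (Cav1.2-like and Cav1.3-like,
separately addressable because different genes encode them), T-type Ca,
the funny current I~f~, a small TTX-sensitive Na current, the rapid
delayed rectifier I~Kr~, Na/K pump, Na/Ca exchange (NCX), a background Na
conductance, and a two-pool Ca subsystem (cytosol + sarcoplasmic
reticulum) with SERCA uptake (`P_up`), voltage-triggered SR release, a
load-dependent SR leak, and Ca-dependent release refractoriness.

### What is calibrated and what is asserted

The two SAN flavours differ in their parameter values.  Four quantities
are *fixed by published characterisations* of the source models rather
than fitted here: the I~f~ half-activation voltage and slope
(mouse −106.8 mV / 16.3 mV, HCN4-like; rabbit −52.5 mV / 9.0 mV, an
HCN1/HCN4 mixture) and the I~f~ reversal potential (−24 mV mouse, −4 mV
rabbit).  The remaining conductances and kinetics were then calibrated,
once, so that the control cells reproduce the published control
behaviour: steady pacemaking at 4.76 Hz (mouse) and 2.90 Hz (rabbit) and
peak inward I~f~ of about 0.006 nA and 0.0067 nA.  That calibration is
part of the model definition — the models *are* "cells that behave like
the published controls" — and the acceptance tests verify that the
shipped parameter sets still produce those numbers by simulation.

During calibration three structural choices proved necessary and are
worth recording:

* **Voltage-triggered SR release.**  A regenerative Ca-induced
  Ca-release gate (release activated by cytosolic Ca) produced a second
  autonomous oscillator that interfered chaotically with the membrane
  clock at many parameter settings.  Release is therefore opened by
  depolarisation (slaved to the action potential) and closed by a slow
  Ca-dependent refractoriness gate; the SR additionally carries a
  load-dependent leak (an overflow valve depending only on the slowly
  varying SR load, so it cannot self-ignite).  The models are membrane-
  clock-driven with a subordinate Ca cycle.
* **Cav1.3 placed in the diastolic window.**  The Cav1.3-like component
  activates near −45 mV, distinctly more negative than the Cav1.2-like
  component (−18 mV), so that L-type gain acts on the diastolic
  depolarisation.  This is the mechanistic reason L-type gain-of-function
  *accelerates* pacemaking in these models, as it must.
* **Short nodal action potential.**  With a long AP, any extra inward Ca
  current lengthens the AP more than it speeds the diastole, inverting
  the chronotropic sign of Ca-channel gain.  The shipped models have
  APD50 ≈ 35–40 ms against cycle lengths of 210/345 ms, which puts the
  cycle-length budget where it belongs — in diastole.

### Known limitations of the reduced SAN models

* The maximum diastolic potential is ≈ −84 mV, deeper than the −55 to
  −65 mV of real nodal cells.  The behaviour-preservation conditions are
  all *relative to control*, so this offset does not propagate into the
  analysis, but absolute AP shapes should not be quoted from these
  models.
* Increasing the SERCA rate `P_up` mildly *slows* these models (uptake
  lowers diastolic Ca, reducing inward NCX; there is no spontaneous
  diastolic release for a fuller store to amplify).  In well-established
  nodal physiology, enhanced Ca cycling speeds pacemaking.  Conclusions
  about ATP2A2-class variants on the cardiac side should therefore be
  drawn cautiously; the package's headline analysis (class-level
  correlation signs) does not depend on this term.
* Ca-handling magnitudes (pool volumes, buffering) are folded into two
  effective constants (`alphaCa`, `betaCa`) rather than resolved
  compartments.
* The pacemaking rate is nearly insensitive to the Cav1.2-like
  component: with a deep MDP and a fast Cav1.3/T-type-driven takeoff,
  Cav1.2 contributes only to the AP itself, so CACNA1C-class variants
  are almost chronotropy-neutral on the cardiac side of this package,
  whereas detailed nodal models show clear effects.  The class-level
  correlation analysis is carried by the Cav1.3, T-type, β-subunit and
  SERCA variants.

### The neuron's gain-reversal mechanism

The neuron couples Ca influx (L- and T-type) to an SK
(Ca-activated K) conductance through a somatic Ca pool cleared at the
SERCA-like rate `P_up`.  More Ca influx → higher intracellular Ca → more
SK → *lower* firing rate: the cell's output gain with respect to Ca
conductance is negative, opposite to the direct depolarising effect of
the same channels in the pacemaker.  This single coupling is what makes
Ca-class variants non-analogous across the two cell types, and it is
asserted by a dedicated mechanism test (SK block strictly raises the
firing rate; L-type gain strictly lowers it).  HCN current is split
between the compartments with slow kinetics (τ = 200 ms), so its gain
depolarises the resting cell and raises the mean rate — the analogous
direction to its pacemaker effect.

## Variant representation and downscaling

A variant is a named set of parameter modifications.  Offsets to
half-(in)activation voltages and reversal potentials are additive (mV);
slope factors, time constants, conductances and pump rates are
multiplicative (dimensionless factor > 0).  Scaling a variant by `s`
multiplies offsets by `s` and raises factors to the power `s`, so
`s = 0` is the exact control, `s = -1` the exactly reversed variant, and
sequential scalings compose additively in the exponent.

Literature-derived variant effects are typically far too strong to
represent a common, well-tolerated polymorphism.  The calibration module
shrinks each variant until the cell barely keeps its behaviour.  For the
neuron, conditions A1–A3 require identical spike counts under three
brief somatic probes whose control responses are 0, 1 and 1 spikes: a
sub-threshold hold (0.5× the control rheobase for 150 ms), a brief
strong pulse that fires exactly one AP (10× for 5 ms), and a short
supra-threshold step whose single-spike count is guarded by the
first-spike latency (2.5× for 32 ms).  The probe design matters: over a
*long* stimulus train, "the same number of spikes" is just frequency ×
time at a tolerance of half a spike, i.e. a disguised zero-tolerance
frequency condition under which no variant could retain a visible
steady-state effect — counts of 0 or 1 with wide latency margins make
A1–A3 genuinely qualitative.  Condition A4 bounds the relative change in
steady firing (±25%) under a sustained DC at 2.5× rheobase, in the flat
part of the f–I curve; measured near threshold instead, the steep f–I
slope amplifies fraction-of-a-millivolt gating shifts into
tens-of-percent rate changes and the condition stops measuring gain.
A5 bounds AP shape on the same sustained trace (peak within 10 mV,
half-width within 25%).  For pacemaker cells, B1 bounds the pacemaking
frequency (±25%) and B2 the AP amplitude (20%) and APD50 (25%) on an
unstimulated recording.  The threshold `c` is the largest scale in
[0, 1] that passes every condition at all probed scales below, found by
an ascending coarse scan plus bisection; non-monotone violation patterns
are resolved by honouring the first violation from below.  The exact
tolerances and stimuli of the original study design are not published,
so the defaults above are declared package defaults, all configurable —
and consequently calibrated `c` values are configuration-dependent and
are never treated as portable constants.

Analyses then run at `epsilon * c` with `epsilon` in {±1/4, ±1/2}:
fractions of the just-tolerable effect, with negative values reversing
the variant's direction.

## The synthetic variant generator

The curated supplementary variant table of the original study design is
not redistributable, so the generator emulates its *structure*: 7 genes
(SCN1A, HCN1, CACNA1C, CACNA1D, CACNB2, CACNA1I, ATP2A2) mapping to
their channels (Na gates; HCN gates/conductance; Cav1.2; Cav1.3; L-type
conductance and inactivation via the β-subunit; Cav3.x; SERCA `P_up`),
a class mixture of 80 Ca/transporter to 14 Na/HCN among 94 variants
(assigned deterministically by rounding), within-class gene weights
proportional to the number of functional studies per gene in the
published study table (CACNA1C 6 : CACNA1D 6 : CACNB2 4 : CACNA1I 2 :
ATP2A2 4; SCN1A 6 : HCN1 3), and one to four parameter modifications
per variant.  Every variant carries its gene's *current-density*
modification (a single factor shared across the gene's subunit targets
— the dominant effect type among curated variants, which are mostly
truncations, knockouts, splice variants and trafficking mutants), plus
up to three additional gating-kinetic modifications.  The CACNB2
density effect applies to both L-type components, since the β-subunit
it encodes partners both α-subunits.  Effect sizes are declared emulation
parameters chosen to span the qualitative variety of reported channel
alterations: voltage offsets uniform on ±10 mV, factors log-uniform on
[1/3, 3].  The same seed always reproduces the same table, and the
generator restores the global RNG state.

What passing tests on synthetic tables do show: the machinery (scaling,
calibration, protocols, aggregation) is correct, and the *sign structure*
of cross-cell-type correlations follows from the models' mechanisms.
What they do not show: agreement with any specific literature variant,
or the numeric correlation magnitudes of the original study (those
depend on the exact 94 curated variants).

## Protocols

* **f–I curve**: somatic DC, default 1 s per amplitude, spike counting
  after a 200 ms onset exclusion (steady firing, not onset bursts).
* **Rheobase**: bisection on a straddling bracket to 1 pA, criterion
  ≥ 1 spike from rest.  Note that single-spike threshold lies below the
  threshold for sustained firing.
* **Pacemaking rate**: 20 s unstimulated integration, first 2 s
  discarded, frequency = (n−1)/(t_last − t_first) over upward 0 mV
  crossings; fewer than 2 crossings is reported as quiescence, a valid
  outcome.
* **Neuron summary statistic**: the mean f–I frequency over a stated
  amplitude range (default 0.35–1.4 nA), which is the quantity the
  cross-model correlations use.

## Tissue models

### 1D chain

Identical SAN cells coupled by a diffusion constant D = 6×10⁴ µm²/ms,
integrated with forward-Euler/Rush–Larsen at Δt = 0.01 ms.  The clamp
protocol holds every cell hyperpolarised, then clamps a fraction to
+23 mV and lets the resulting wave run.  The published protocol's holding
potential of −64 mV presupposes nodal cells whose firing takeoff lies
above it; for this package's deep-MDP reduced models −64 mV is already
suprathreshold, so the default pre-clamp is −80 mV, which plays the same
"just below the diastolic range" role (the pulse potential is unchanged).
Conduction velocity is the least-squares slope of position against
activation time over interior cells.  Because the cells are pacemakers,
the substrate drifts toward threshold after release and the wave slowly
accelerates; velocity *comparisons* (e.g. the √D scaling law) are
therefore made over matched post-release epochs, where the drift cancels
and the continuous-cable prediction CV ∝ √D is recovered to within a
fraction of a percent.  The cell length needed to convert cells/ms into
µm/ms is not a published quantity; 70 µm per cell is the declared
convention.

### 2D monodomain SAN-in-atrium

A 3×3 cm sheet with anisotropic diffusion (1.2 cm²/s along the monitored
fiber, 0.25 cm²/s across), a central SAN disc of radius 0.27/0.34/0.40 cm,
and no-flux boundaries, solved by operator splitting: per-node reaction
(full pacemaker model inside the disc, Rush–Larsen gates; a
three-variable Fenton–Karma-type atrial membrane model outside, mapped to
physical mV by V = V₀ + 100·u) followed by an explicit finite-difference
diffusion step.  The desk-scale grid is 76×76 nodes (0.04 cm) at
Δt = 0.125 ms with 2 reaction substeps; the published resolution
(151×151, 0.02 cm) is available as the `"full"` preset.  Finite
differences replace finite elements; on a square with no-flux boundaries
the scheme choice is immaterial at these resolutions.

Two spatial-design choices place the tissue at the operating point the
study design requires:

* **Centre-to-periphery gradient.**  The pacemaker drive conductances
  (both L-type components, T-type, I~f~, Na) ramp linearly from full
  strength at the disc centre to 25% at the rim.  A homogeneous disc
  proved practically un-silenceable — its interior ignores boundary
  load — whereas real nodes grade from central to peripheral cell types.
  The published spatial profile is not available; this ramp is the
  package's approximation.
* **Atrial operating point.**  The atrial resting potential (−86 mV) and
  fast-inward time constant (τ_d = 0.297 ms) were chosen, at design
  time, so that control tissue conducts 1:1 at every studied radius
  while both failure margins lie within reach of calibrated variant
  effects: a strong loss-of-function Ca-channel application (ε = −1/2)
  silences the small (0.27 cm) node outright, and a strong
  gain-of-function application (ε = +1/2) produces sinoatrial exit block
  in the large (0.40 cm) node — conducted beats early on, then
  progressive block with a lengthening atrial interval.  These margins
  are razor-thin by the nature of source–sink balance; the package
  deliberately ships the configuration on the operating point rather
  than pretending the phenomenon is robust to arbitrary tissue
  parameters.  One known deviation: the gain-of-function variant also
  shows some block at the intermediate radius (0.34 cm), where the
  reference design reports all variants stable.

Exit-block detection pairs each SAN cycle (upward −20 mV crossing at the
disc centre; electrotonic load flattens the nodal AP below the
single-cell 0 mV criterion) with an atrial activation (upward −40 mV
crossing at the border probe) inside a 150 ms causality window; an
unmatched SAN cycle is a block event.  Silencing is the absence of SAN
cycles after the settling period.

## Numerical choices

* **Single-cell integration**: `deSolve::lsoda` (variable-step, stiff-
  capable) on compiled right-hand sides, rtol = atol = 10⁻⁸ by default.
  The defaults are validated by a refinement invariant: tightening both
  tolerances tenfold changes the measured pacemaking frequency by less
  than 0.1% (observed: < 10⁻⁷ relative).  Runs are bit-reproducible:
  fixed solver, fixed tolerances, no wall-clock dependence.
* **Blow-up policy**: |V| > 200 mV, non-finite states, or non-positive
  concentrations abort with an error naming the offending variable; gate
  trajectories are checked post hoc to remain in [0, 1].
* **Spike detection**: upward threshold crossing (−20 mV neurons, 0 mV
  single-cell SAN cycles) with linear interpolation and a 2 ms
  refractory; the detection rules are package conventions, stated here
  because no published convention exists.
* **Transient handling**: the first 2 s of every pacemaker recording and
  the first 200 ms after stimulus onset are discarded before frequency
  or shape measurement.
* **Tissue stepping**: Rush–Larsen exponential gate updates allow the
  0.0625 ms reaction substep; the explicit diffusion step satisfies its
  stability bound by construction and is charge-conserving under no-flux
  boundaries (asserted to solver precision in the tests).
* **Calibration resolution**: scan step 0.1 and bisection tolerance 10⁻³
  by default; the end-to-end pipeline uses a coarser, configurable
  resolution (step 0.25, tolerance 0.05) because per-variant `c` enters
  the analysis only through `epsilon * c`, where per-mille precision is
  immaterial.
* **Problem sizes**: the shipped tests run the 30-variant pipeline at
  ε = −1/4 on a 5-point amplitude grid, 4 s pacemaker recordings for
  condition evaluation, a 100-cell cable, and 3.5–4 s desk-grid 2D
  simulations; these sizes were chosen to exercise every code path at
  full scientific fidelity while keeping a complete run on a single CPU
  practical.

## What the headline analysis computes

For each variant and each cell model, the pipeline calibrates `c`,
applies the variant at ε = −1/4, and records the neuron mean rate and the
SAN pacemaking rate.  Per gene class it reports the Pearson correlation
between the two columns (inapplicable variants dropped whole, never
partially applied) and classifies each variant as analogous (same-sign
changes), non-analogous (opposite), or neutral (inside a 1% dead-band
that absorbs numerically meaningless signs; the original design used no
dead-band, so borderline classifications can differ).  The acceptance
suite asserts the sign structure — Na/HCN positive, Ca/transporter
negative — which is the package's headline reproduction; the numeric
magnitudes depend on the variant set and are not asserted.

A caveat on sample size: at 30 variants the 80:14 class mixture leaves
only about four Na/HCN variants, so that class's correlation rests on a
small sample and its sign is not stable across arbitrary generator
seeds (the Ca/transporter class, with ~26 variants, is robust).  Larger
tables sharpen both; the reference design itself used 14 Na/HCN
variants among 94.
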