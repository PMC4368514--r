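---
title: "Methods: the Hb-Kr dual-regulation patterning model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Hb-Kr dual-regulation patterning model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`hbkr` simulates regulation of the gap gene *hunchback* (*hb*) by
Bicoid (Bcd), Hb itself and Krüppel (Kr) over the first 40 minutes of
nuclear cleavage cycle 14, on a lattice of (5 µm)³ subvolumes spanning
20–80 %EL of the anterior–posterior axis. Gene regulatory state is
molecular: the *hb* cis-regulatory region carries two Hb sites (state
`h0/h1/h2` = number bound) and two Kr sites (`kr0/kr1/kr2`); the *Kr*
region carries one Bcd site (`KrB0/KrB1`) and two Hb sites
(`KrH0/KrH1/KrH2`). Binding and unbinding are elementary reversible
reactions; transcription propensities are gated on the joint bound
state; translation, mRNA/protein decay and nearest-neighbour protein
diffusion complete the scheme. In the wild-type (`kr_dual`) wiring:

* *hb* transcribes from `h1·kr0` (k5), `h2·kr0` (k6) and — the dual
  activation — `h2·kr1` (k16); both `kr2`-states and `h1·kr1` are
  silent. A position-dependent basal channel represents Bcd activation
  (below).
* *Kr* transcribes only from `KrB1·KrH0` (k24): Bcd activates, any
  bound Hb silences.
* Only the proteins diffuse (jump rate D/h²: Hb 1.2·10⁻³ s⁻¹, Kr
  1.2·10⁻² s⁻¹ per neighbour); mRNA does not. Lattice boundaries are
  reflecting in AP and DV — the window is an excised mid-embryo region,
  and zero-flux is the least-structured closure.

All unbinding constants are 1 s⁻¹, so binding constants are relative
affinities. Second-order constants are tabulated in molar units and
converted at compile time to per-molecule-pair propensity factors,
`k' = k / (N_A · V)` with `V = (5 µm)³ = 1.25e-13 L`. This volume is the
single unit-conversion constant of the model; with it, the tabulated
decay (k7 = 6.8e-3 s⁻¹, k9 = 6e-3 s⁻¹) and translation
(k8 = 0.3125 s⁻¹, a 1:50 mRNA:protein efficiency) constants carry
~100 initial mRNA copies to ~140 by mid-NC14 and ~7000 protein copies
per nucleus, on the observed timescale.

Mechanism variants (`kr_null`, `mut_inh`, `static_kr`, `hb_dual`,
`dual_dual`, `no_kr`) rewire which bound states transcribe and which
genes are dynamic; see `?compile_reactions`. The *Kr-* mutant is
`kr_null`: k10 = k12 = 0, removing every reaction that touches Kr on
the *hb* enhancer.

## The lumped Bcd activation term

The Bcd-dependent component of *hb* transcription is inherited, in the
full treatment, from a six-Bcd-binding-site enhancer sub-model whose
constants are external to this package. We represent it as a static,
position-dependent zeroth-order channel

```
alpha_B(x) = a_B · B(x)^n / (B(x)^n + K^n),   B(x) = B0 · e^-(x - 20)/lambda
```

with `(a_B, n, K, B0, lambda)` as explicit calibration knobs
(`bcd_params()`). The channel is constant in time; whether
Bcd-dependent transcription decays during NC14 is left out of the model
(a known simplification, flagged rather than guessed).

Calibration targets pin these knobs (and they were fixed once, before
the stochastic analyses): the deterministic Kr-null boundary at 44 %EL
at 40 min; the wild-type boundary at 51 %EL, PS4 peak at 48 %EL,
Kr peak at 55 %EL, trough/peak ratio 0.89; anterior mRNA ≈ 140 and
protein ≈ 7000 per nucleus. The shipped defaults are `a_B = 0.16`
copies/s, `n = 8`, `K = 1500`, `B0 = 3000`, `lambda = 30 %EL`. Two
consequences of this structure are worth knowing:

* The *Kr* gene's Bcd channel (k18·B) and the basal *hb* channel share
  one gradient. Because k18 is fixed, the gradient's absolute scale is
  pinned by the requirement that the mid-embryo Kr domain reaches the
  amplitude at which the second Kr binding (`kr2`) can terminate the Hb
  domain; the steady Kr peak is then comparable to the Hb plateau
  (within ~25%), consistent with the relative gap-protein intensities
  the constants were tuned against.
* Anterior Kr is not zero. The `KrH0` occupancy at anterior Hb levels
  (~2.5%) leaks enough *Kr* transcription that anterior Kr settles
  near 500 copies, partially occupying `kr1` on *hb*. The anterior
  wild-type level (~140 mRNA) therefore *includes* a k16 contribution;
  the Kr-null anterior settles lower (~85 mRNA), in line with the
  reduced *hb* intensity of *Kr-* mutants.

## Initial conditions

The t = 0 state (`initial_profile_params()`, `initial_state()`)
emulates end-of-NC13 expression: *hb* mRNA and protein as anterior-high
logistic sigmoids (maximum 100 and 4200 copies; half-height 48 %EL,
scale 2 %EL), *Kr* mRNA/protein as a Gaussian bump centred at 55 %EL
(σ = 6 %EL) at 60% of the calibrated mid-NC14 amplitudes (9000 protein
/ 150 mRNA at the peak), all gene states unbound, DV-uniform. The
`fraction` parameter (default 0.6) scales the bump amplitudes relative
to their mid-NC14 reference; the *hb* amplitudes are specified directly
as t = 0 values since those are the quantities known per se. The
initial sigmoid position is a calibration knob: with the tabulated
constants the Kr-null profile retreats ~4 %EL over 40 minutes to its
basal anchor while the wild type is stabilised by the Kr wiring, and
half-height 48 %EL places both end points correctly. Stochastic initial
counts are deterministic rounds of the same profiles — replicate
variation enters only through trajectory noise, matching the premise
that the studied variability is intrinsic expression noise.

What the generator does *not* emulate: embryo-to-embryo variation in
the Bcd gradient or initial profiles (extrinsic noise), nuclear
divisions, mitotic pauses, or the geometry of a real blastoderm
surface. Passing tests therefore speak to intrinsic-noise behaviour of
the regulatory circuit, not to total biological variability.

## Engines

**Deterministic.** Mean-field mass-action ODEs with gene states as
continuous occupancy fractions in [0, 1], integrated by classical
fixed-step RK4 in compiled code. The stiffest channel is the second Hb
binding on *Kr* at anterior protein levels (k22'·H ≈ 750 s⁻¹), which
bounds the stable step at ≈ 2.8/750 s; the default `dt = 0.003` s sits
under that with margin. Negative excursions smaller than `neg_tol`
(10⁻⁴ copies) are clipped to zero; anything larger aborts the pass and
the integrator halves `dt` and restarts. Halving the step changes
recorded values by < 10⁻⁴ relative (tested), and pure-decay runs match
the closed form to 10⁻⁶ relative.

**Stochastic.** The exact next-subvolume method: per-subvolume summed
propensities, next-event times in an indexed 4-ary min-heap, reaction
vs diffusion channel chosen by inverse sampling within the firing
subvolume, neighbour times rescaled by the standard propensity-ratio
rule. Propensity sums are updated incrementally through a
species→reaction dependency graph and refreshed periodically against
floating-point drift. Each replicate owns a xoshiro256++ generator
seeded by splitmix64 from `base_seed + replicate index`, so ensembles
are reproducible and order-independent. Snapshots are the state at the
last event at or before each record time (piecewise-constant sampling).
A 1D wild-type run to 2400 s executes ~4·10⁷ events in a few seconds;
2D two-locus runs execute ~5·10⁸ events.

Exactness is part of the design: no tau-leaping or hybrid
approximation is used anywhere, and the suite checks the Poisson
stationary law, exponential inter-event times, mass conservation under
diffusion, and convergence of the ensemble mean to the ODE solution as
copy numbers scale up.

## Two-locus mode

For within-nucleus transcript noise, each nucleus carries two
independent transcription loci (A and B): gene-state species and mRNA
pools are duplicated per locus, proteins are pooled. The one-locus
calibration lumps both gene copies, so per-locus transcription channels
run at half the one-locus rate; pooled output then matches the
deterministic calibration exactly, and per-locus mRNA (~70 anterior)
is what a transcription-dot measurement would see. The noise statistic
is the standard deviation of the relative A/B difference over nuclei
with both loci active within ±5 %EL of the Hb boundary; one nucleus is
one subvolume, per the model's resolution.

## Reversed-wiring variants

In `hb_dual` and `dual_dual`, *Kr* is activated by the first Hb
binding (`KrH1`) instead of Bcd. The tabulated Hb-binding constants on
*Kr* (weak first, strong second) were calibrated for the repressive
role and leave `KrH1` rare, so the channel carries a calibration
multiplier `krh1_scale` (default 25), set once so the Hb-activated Kr
domain is expressed at mid-embryo scale. With it, `hb_dual` yields an
unrefined Hb step with no PS4, and `dual_dual` shows the hallmark
behaviour of a boundary that keeps drifting posteriorly between 30 and
40 minutes — the instability that motivates anchoring *Kr* to the
static Bcd gradient in the wild-type wiring.

## Analysis conventions

* **Boundary**: anterior-most AP position where a profile crosses from
  ≥ half of its maximum to below it, linearly interpolated between
  subvolume centres. The half-height reference is the profile maximum
  over the analysed window at that time.
* **PS4 peak**: maximum in 40–55 %EL, required to be a strict local
  maximum after 3-point smoothing (damping single-event spikes);
  absence of such a maximum is a result ("no peak"), not an error. The
  Kr peak is a plain argmax.
* **Ensemble boundary statistics**: for stochastic profiles,
  `positional_sd()` applies the same 3-point smoothing before locating
  the crossing. Without it, a single subvolume whose count happens to
  dip below half for one snapshot registers as an anterior "boundary"
  several %EL from the domain edge; such one-subvolume spikes are
  sampling artefacts of reading a noisy profile at nuclear resolution,
  exactly what the smoothing in the peak rule exists for. Smoothing is
  applied identically to both conditions and is switchable
  (`smooth = FALSE`).
* **Interface stability** (`interface_variability()`): SD of the
  boundary position across 1-minute snapshots over minutes 30–40, per
  replicate. A per-subvolume count CV is not used because it conflates
  noise with mean expression level near a steep boundary.
* **F-test**: two-sided (larger variance over smaller, doubled tail
  probability), with the one-sided value also reported, since the
  directional hypothesis is stated in advance.

## Problem sizes and defaults in the shipped checks

The packaged tests and the acceptance script use: deterministic runs on
the 60-subvolume lattice to 2400 s; 1D stochastic ensembles of n = 25
per condition; 2D two-locus runs (60×10) with n = 3 per condition; and
n = 200 replicates for the small-network distributional oracles. These
sizes put every distributional check within a few standard errors of
its target while keeping a full run on one CPU in the tens of minutes.
The full n = 12 two-locus comparison of the complete analysis is
available through `experiment_locus_noise(n = 12)`.

## Known limitations

* The wild-type boundary carries a deliberate posterior bias: early
  snapshots match early-NC14 data and the final boundary sits at
  51 %EL, a few %EL posterior of fixed-embryo measurements — the cost
  of letting the same constants produce the *Kr-*-to-WT intensity
  doubling and peak positions.
* Between-replicate boundary SDs separate the conditions clearly at 20
  and 40 minutes (Kr-null/WT ≈ 1.5–1.8×), but **not at 7 minutes**: at
  t = 420 s protein has turned over for only ~2.5 lifetimes and the
  boundary position is still dominated by the shared deterministic
  initial profile, so the two conditions' SDs are statistically
  indistinguishable there (ratio 0.9–1.0 across seed sets). Early
  separation would require either differing initial conditions or
  faster protein turnover; with the tabulated constants and a common
  t = 0 state it does not occur.
* The lumped basal channel is a single zeroth-order reaction; the full
  multi-site Bcd enhancer machinery would add its own binding noise
  and permit Bcd-dependent shutoff during NC14.
* Rate constants are relative, not absolute: the nuclear-resolution
  subvolume makes single bound-state "molecules" extremely dilute, so
  second-order constants are correspondingly inflated. The model
  predicts relative regulatory rates and noise structure, not binding
  biochemistry.
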