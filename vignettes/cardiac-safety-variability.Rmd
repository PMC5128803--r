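---
title: "Modeling inter-individual variability in cardiac drug safety"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling inter-individual variability in cardiac drug safety}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Drug-induced torsades de pointes is rare even for compounds that block the
hERG channel in everyone. A simulation run at population-mean parameters
reproduces the mean response — moderate action-potential (AP)
prolongation — and misses the vulnerable individuals in whom the same
block triggers early afterdepolarizations (EADs), the cellular arrhythmia
trigger. `torsim` models two concrete sources of that vulnerability:

* **intracellular spermine**, the polyamine that produces the inward
  rectification of I~K1~; its circulating level varies almost five-fold
  with diet and age, and I~K1~ is as load-bearing for repolarization
  reserve as I~Kr~;
* **L-type Ca^2+^ conductance** (G~CaL~), which varies about two-fold
  across individuals through polymorphisms and mutations.

The package simulates single cells under multichannel conductance block
while sweeping these two parameters, detects EADs and spontaneous
activity directly, and aggregates the result into risk classifications
and an extreme-value population risk.

## The cell models

Two reduced Hodgkin–Huxley models are implemented: an endocardial
ventricular cell (8 states: V, m, h, d, f, x~r~, x~s~, Ca~i~) and a
Purkinje cell (9 states: + y). They are deliberately compact
formulations, built and calibrated for this package, that contain every
current with a role in the analysis:

| Current | Form | Role |
|---|---|---|
| I~Na~ | g~Na~ m³h² (V − E~Na~) | upstroke, excitability |
| I~CaL~ | g~CaL~ · s · d f (V − E~CaL~) | plateau; the reactivating window current that carries EADs |
| I~Kr~ | g~Kr~ x~r~ r~∞~(V) (V − E~K~) | dominant repolarizer; the torsadogenic drug target |
| I~Ks~ | g~Ks~ x~s~² (V − E~K~) | slow reserve current |
| I~K1~ | g~K1~ √(K~o~/5.4) u(V, SPM) (V − E~K~) | terminal repolarization and resting stability |
| I~b~ | g~bNa~ (V − E~Na~) | background inward leak |
| I~f~ (Purkinje) | g~f~ y (V − E~f~) | diastolic depolarization |

with s = 0.038 (A/F)/(pS/pF·mV) converting the pharmacological G~CaL~
axis (1.5–3 pS/pF) to current density. All potentials are in mV
(intracellular minus extracellular), currents in A/F (outward positive),
time in ms; temperature is fixed at 310 K and extracellular ions at
K~o~ = 5.4, Na~o~ = 140, Ca~o~ = 1.8 mM.

**Spermine block of I~K1~.** The unblocked fraction is a Woodhull-type
voltage-dependent binding equilibrium,

$$u(V, \mathrm{SPM}) = \frac{1}{1 + [\mathrm{SPM}]/K_d(V)},
\qquad K_d(V) = K_{ref}\, e^{-(V-E_K)/k_v},$$

with K~ref~ = 24 µM and k~v~ = 13 mV calibrated once so that at the
population-mean 3 µM the I~K1~–V relation is physiological: near-ohmic at
rest, peak outward current around −60 mV, essentially silent positive of
−20 mV. Block is monotone in spermine at every depolarized potential (a
property test asserts this), so raising SPM from 3 to 5 µM removes a
fixed fraction of terminal-repolarization current — the experimentally
motivated "metabolic" lever. Spermine enters the model nowhere else.

**Why a reduced formulation.** The analysis needs a model whose
repolarization reserve responds correctly to (SPM, G~CaL~, channel
block), not a transcription of any particular published ionic model. The
reduced models were calibrated once, before the test suite was written,
against the qualitative study conditions: a stable 0.5 Hz limit cycle
with a normal-looking AP at every control grid cell; moderate
prolongation *without* EADs under 90% g~Kr~ block at nominal parameters;
EAD generation in the repolarization-compromised corner of the
variability grid; monotone aggravation with block depth; and
spermine-step-triggered sustained arrhythmia under deep (>92%) I~Kr~
block. The EAD mechanism is the classical one: when repolarization
through the −10…−40 mV range is slow enough, the f gate of I~CaL~
recovers while the d gate still conducts, and the window current
re-depolarizes the membrane.

Frozen endocardial parameters: g~Na~ = 12, g~Kr~ = 0.12, g~Ks~ = 0.006,
g~K1~ = 0.09, g~bNa~ = 0.002 nS/pF, G~CaL~ = 2.0 pS/pF, SPM = 3 µM.
The Purkinje variant differs in g~K1~ = 0.05 (the weak inward rectifier
characteristic of Purkinje fibers, giving a depolarized diastolic
potential near −76 mV) and g~f~ = 0.004 with E~f~ = −20 mV. Its
automaticity is sub-threshold by construction: the funny current
depolarizes diastole slowly but does not reach threshold within the
0.3 Hz pacing cycle, so paced beats are unambiguously stimulus-attributed
— the package's resolution of how pacing and automaticity interact.

## Protocols

* **Steady pacing** — 0.5 Hz (endocardial) or 0.3 Hz (Purkinje), chosen
  because bradycardia potentiates drug-induced EADs (bradycardia-dependent
  torsades); 90 beats (3 min) of pre-pacing at 0.5 Hz before any
  measurement; the final 3 beats recorded at 0.5 ms output resolution.
* **Stimulus** — 1 ms square pulse at 1.5× the diastolic threshold; the
  threshold is found once per model by bisection (12 halvings of
  [0.5, 120] A/F) from the stored diastolic equilibrium and cached.
* **Spermine step** — continuous 0.5 Hz pacing for 6 min with SPM
  switched from 3 to 5 µM at 3 min; arrhythmia means any spontaneous
  (non-stimulus-aligned) depolarization — an EAD in any beat or a
  spontaneous upstroke — with signed latency from the switch.
* **Variability grid** — SPM {1, 2, 3, 5} µM × G~CaL~
  {1.5, 2.0, 2.5, 3.0} pS/pF. The spermine axis spans the five-fold
  dietary spread containing the 3 µM mean and the 5 µM step level; the
  G~CaL~ axis is the stated two-fold polymorphism range. One steady-pacing
  run per cell; the per-cell EAD flag is taken over all recorded beats.
* **Population scan** — all 3ⁿ combinations of
  {mean − 3 SD, mean, mean + 3 SD} over n parameters. Each extreme level
  represents 0.2% of the population (above or under mean ± 3 SD), so if
  the minimal arrhythmic combination has n′ parameters at extremes the
  population risk is 0.002^n′^ (0 if no combination is arrhythmic).
  Levels falling below a parameter's floor are clipped and flagged. The
  arrhythmia predicate is injectable (`outcome_fn`), which keeps the
  combinatorics testable in milliseconds and lets users substitute their
  own endpoint.

## Biomarkers and detection conventions

* APD~level~ = time from the maximum-upstroke instant to the first
  crossing of rest + (1 − level/100)·amplitude, linearly interpolated on
  the output grid; failure to reach the level before the window ends is
  flagged `incomplete` and reported as the window length.
* Triangulation = APD90 − APD40. "Triangulation present" in the paired
  drug-vs-control comparison means Δ(APD90 − APD40) > 20% of the control
  value — the field names the phenomenon without a formula, so the
  threshold is a declared package convention.
* EAD = a local minimum of V followed by ≥2 mV of re-depolarization
  sustained ≥5 ms, occurring after 30% and before 100% repolarization and
  outside the stimulus artifact (first 10 ms after stimulus onset).
  Spontaneous upstrokes are contiguous runs of dV/dt > 5 mV/ms outside
  stimulus-aligned windows.
* Simulation-based risk groups (precedence A1 > A2 > B > C): A1 if
  ΔAPD90 > +40%; A2 if triangulation present with ΔAPD90 ≥ 0; B for
  unexacerbated prolongation (above a ±5% no-effect band, up to +40%) or
  triangulation with shortening; C for shortening or no effect. The
  ±5% band exists because a floating-point pipeline never returns an
  exact zero.

## Numerical choices

* `deSolve::lsoda` (adaptive stiff), rtol 10⁻⁶ / atol 10⁻⁸; halving the
  tolerances moves APD90 by far less than 0.5 ms (asserted by a test).
* Integration is beat-segmented: each stimulus edge is a segment
  boundary, so the square pulse is represented exactly rather than
  through a max-step constraint. Pre-pacing beats produce only endpoint
  output; recorded beats a dense 0.5 ms grid (1 ms for the 6-min step
  protocol).
* Gating variables are projected back onto [0, 1] after each solver
  segment; violations beyond 10⁻⁵ (far above the O(rtol) upstroke
  overshoot this guards against) abort the run.
* Near the EAD boundary the model can settle into 2:1 alternans — EADs
  on every other beat. All recorded beats (3 by default) therefore
  contribute to a cell's EAD flag; a single-beat rule would make the
  outcome depend on recording parity.
* The stored initial states are the stimulus-free diastolic equilibria,
  relaxed to |d/dt| < 10⁻¹⁵; a root-finding test verifies they
  annihilate the right-hand side.

## Synthetic population and drug library

The default spermine population is normal(3, 0.75) µM clipped at 0: the
five-fold observed spread then spans roughly mean ± 2 SD, and
mean + 3 SD marks the rare high-spermine individual. The SD is a declared
convention (the source data are reported only as a spread); a
moment-matched lognormal alternative is provided because measured
polyamine distributions are right-skewed. Sampling is seed-local (the
global RNG state is untouched).

The 11-compound reference library ships with literature-derived
*configuration* IC50s and test concentrations, provenance-marked in the
CSV; the tests assert only the schema and the clinical group labels,
never the potency numbers. Synthetic group-typical profiles
(`make_synthetic_drug`) are generated for classifier testing: their pD2
patterns land on the tree branch characteristic of each group by
construction.

The decision tree is implemented literally, including the branch that
flags *weak* (pD2 < 6) pure I~Kr~ blockers as A1 candidates while potent
pure blockers fall through to simulation — arguably inverted in intent,
but it is the published rule; the trail records the literal reading so
downstream users can see which branch fired.

## What the tests do and do not show

The synthetic conditions reproduce the *mechanisms* — conductance-block
pharmacology, spermine-graded repolarization reserve, window-current
EADs, bradycardia-dependent aggravation — under a reduced model
calibrated to the study's qualitative outcomes. Quantities tied to a
specific published ionic model (absolute APDs, drug-specific latencies,
exact IC50s) are configuration, not predictions; passing tests show the
pipeline's logic and the phenomenology, not clinical accuracy for a
specific compound. Known limitations: single cells only (no conduction,
no reentry, hence I~Na~ block is under-weighted by construction); no
pharmacokinetics or metabolites; conductance-scaling block only (no
state-dependent or trafficking effects); two cell types; two variability
axes. Problem sizes — 90-beat pre-pacing, 16-cell grids, 6-min step
runs, 10⁵-draw sampler checks — are the package's standard study
conditions and keep a full verification run in the minutes range on one
CPU.
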