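# torsim

Variability-aware in silico cardiac safety screening in R.

Most drug-induced torsades de pointes (TdP) casualties are rare: a compound
that blocks the hERG channel (I_Kr) prolongs the QT interval in everyone but
triggers arrhythmia only in a vulnerable few. Conventional single-cell
simulations run at population-mean parameters and therefore miss exactly
those individuals. `torsim` puts the inter-individual variability back in:
it simulates human endocardial and Purkinje action potentials under
multichannel conductance block while varying two biologically grounded
parameters — intracellular **spermine** (which sets the rectification of
the inward-rectifier current I_K1 and varies up to five-fold with diet,
age, and metabolic state) and the **L-type Ca²⁺ conductance** G_CaL
(which varies about two-fold with polymorphisms) — and looks for the
actual cellular arrhythmia trigger, early afterdepolarizations (EADs),
rather than only for surrogate markers.

It is aimed at safety-pharmacology modelers who want to ask not "does this
compound prolong the AP?" but "in which corner of the population does it
become arrhythmogenic, and how rare is that corner?".

## The model and methods in brief

* **Cell models** — reduced Hodgkin–Huxley models (8 states endocardial,
  9 states Purkinje) carrying I_Na, I_CaL, I_Kr, I_Ks, a background Na⁺
  leak, the Purkinje funny current I_f, and a spermine-rectified
  I_K1:

  I_K1 = g_K1 · √(K_o/5.4) · (V − E_K) · 1/(1 + [SPM]/K_d(V)),
  K_d(V) = K_ref · e^−(V−E_K)/k_v,

  so depolarization and spermine jointly block the channel — the classic
  polyamine mechanism of inward rectification. Raising spermine erodes the
  repolarization reserve exactly where EADs take off.
* **Drug block** — the conductance-block formula
  G = G_max / (1 + ([D]/IC₅₀)^n), Hill n = 1 by default; I_K1 block is a
  fractional scale. pD2 = −log₁₀(IC₅₀).
* **Protocols** — slow pacing (0.5 Hz endocardial / 0.3 Hz Purkinje,
  the bradycardia-dependent-TdP regime) with 3 min pre-pacing; a
  3 → 5 µM spermine step (3 min + 3 min); a 4×4 spermine × G_CaL
  variability grid; and a 3ⁿ extreme-value population scan whose risk is
  0.002^n′ (each extreme level represents the 0.2% tail of a parameter's
  population distribution).
* **Biomarkers** — APD30/40/50/90, triangulation (APD90 − APD40),
  upstroke velocity, EAD detection (≥2 mV re-depolarization between 30%
  and 100% repolarization), spontaneous-event detection.
* **Risk classification** — a pD2-threshold decision tree plus the
  simulation-based grouping: A1 (>40% APD prolongation), A2
  (triangulation without shortening), B (moderate prolongation or
  triangulation with shortening), C (shortening or no effect).

## Worked example

```r
library(torsim)
model    <- make_model("endocardial")
protocol <- default_protocol(model)   # 0.5 Hz, 90 pre-pacing beats

control <- run_paced_to_steady(model, protocol = protocol)
blocked <- run_paced_to_steady(model, drug = directive_block("g_Kr", 90),
                               protocol = protocol)
m_ctl <- ap_metrics(segment_beats(control)$windows[[3]])
m_blk <- ap_metrics(segment_beats(blocked)$windows[[3]])
effect <- compare_effects(m_ctl, m_blk)
```

prints, via `sprintf` on the metric fields:

```
control APD90  571.5 ms
90% block APD90 939.5 ms (+64%), EAD: FALSE
```

At population-mean parameters, even a dofetilide-grade 90% I_Kr block only
prolongs the AP — no arrhythmia trigger, the classic false-negative of
mean-parameter modeling. The variability grid finds the vulnerable
individual:

```r
grid <- run_variability_grid(model, directive_block("g_Kr", 90),
                             protocol = protocol)
grid$ead_count                         # 1  (of 16 cells)
subset(grid$cells, ead)                # spm = 5 uM, g_CaL = 3 pS/pF
```

Only the high-spermine / high-G_CaL individual — 1 of the 16 parameter
combinations — develops EADs. The decision tree triages compounds before
any simulation is spent on them:

```r
print(classify_by_tree(default_drug_library()$quinidine))
#> <torsim_tree: NEEDS_SIMULATION >
#>   - I_Kr blocked, pD2 = 6.15
#>   - pD2(I_Kr) >= 6: test I_CaL
#>   - I_Na/I_Ks/I_K1 sensitive: simulate to discriminate
```

The shipped 11-compound library (`default_drug_library()`) carries
literature-derived IC50 configuration values (see its `provenance`
column) and the clinical risk-group labels used as expected values in the
tests.

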