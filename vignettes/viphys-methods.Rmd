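---
title: "Modelling and classifying VIP interneuron firing patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and classifying VIP interneuron firing patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viphys)
```

Vasoactive intestinal peptide expressing interneurons (VIP-INs) of
neocortical layer 2/3 split into two firing phenotypes when driven with
long (8 s) current steps: *continuous adapting* (CA) cells fire
throughout, while *irregular spiking* (IS) cells fire an initial burst,
pause, and then spike irregularly. The IS phenotype depends on M-current
(a slow, non-inactivating K⁺ current carried by KCNQ channels), and IS
cells are selectively impaired when one *Scn1a* allele — encoding the
Na⁺ channel Nav1.1, the gene mutated in Dravet syndrome — is lost.
`viphys` implements the computational side of that story: a
conductance-based model of the interaction between Na⁺ current density
and M-current, the patch-clamp feature battery used to phenotype such
recordings, the unsupervised IS/CA classifier, a synthetic-cohort
generator, and the associated group statistics.

## The model

A single compartment with Hodgkin–Huxley Na⁺ and delayed-rectifier K⁺
conductances plus one slow K⁺ conductance `gKS` standing in for
M-current:

$$c_m \frac{dV}{dt} = g_{leak}(E_l - V) + m^3 h\, g_{Na}(E_{Na} - V)
  + n^3 g_{KDR}(E_K - V) + s\, g_{KS}(E_K - V)
  + \frac{I_{inj} + I_{noise}}{A}$$

Each gate follows $dx/dt = (x_\infty - x)/\tau_x$ with
$x_\infty = \alpha/(\alpha+\beta)$ and $\tau_x = 1/(\alpha+\beta)$; the
rate expressions are printed in `?rate_constants`. The slow gate `s`
activates with a fixed $\tau_s = 300$ ms around a half-activation of
−35 mV, so it integrates firing over hundreds of milliseconds: once a
cell has fired for a while, `s` builds up, opposes the injected current,
and can silence the cell until it decays again. That slow negative
feedback — helped along by current noise — is what produces burst /
pause / irregular-spiking dynamics at high `gKS`, and plain spike
frequency adaptation at low `gKS`.

Note the delayed rectifier uses $n^3$, not the classic squid $n^4$; the
exponent is exposed as `kdr_exponent` in `model_parameters()`.

### Parameters, units and defaults

| parameter | default | units | meaning |
|---|---|---|---|
| `g_leak` | 0.03 | mS/cm² | leak conductance (high input resistance) |
| `g_na` | 65 | mS/cm² | Na⁺ density; halved to model *Scn1a*⁺/⁻ |
| `g_kdr` | 5 | mS/cm² | delayed rectifier |
| `g_ks` | 2 | mS/cm² | slow (M-like) K⁺; ~0 in CA-like, ~2 in IS-like cells |
| `e_leak`, `e_k` | −70 | mV | leak (Cl⁻) and K⁺ reversals |
| `e_na` | 50 | mV | Na⁺ reversal |
| `tau_s` | 300 | ms | slow-gate time constant |
| `noise_amplitude` | 10 | pA | noise-current cap; per-step Gaussian, sd = cap/3, clipped at ±cap |
| `c_m` | 0.75 | µF/cm² | specific capacitance (calibrated, see below) |
| `area` | 2×10⁻⁵ | cm² | membrane area (calibrated, see below) |

### Calibrating `c_m` and `area`

The conductance densities, reversals and τ_s above are fixed by the
model's published description; capacitance and membrane area are not,
and they decide how an injected current in pA maps onto current density.
We calibrated them against the model's published behaviour at its
600 ms × 100 pA test pulse: with `c_m = 0.75` µF/cm² and
`area = 2e-5` cm², halving `g_na` at `g_ks ≈ 0` costs ~11% of
steady-state firing and ~18% of spike height (the "minimal impairment"
regime), while at `g_ks = 2` the halved-`g_na` cell collapses after a
few spikes — and the high-`g_ks` cell spikes irregularly at moderate
drive.

This calibration has a cost that we state plainly: it fixes the cell's
input resistance at `1/(g_leak · area)` ≈ 1.7 GΩ and its rheobase at
~20–30 pA, several-fold away from measured VIP-IN values (~350 MΩ,
~50 pA). With the published `g_leak`, no `(c_m, area)` pair can match
the measured passive scale *and* the published 100 pA firing
phenomenology simultaneously — the published behaviour requires 100 pA
≈ 5 µA/cm², the measured input resistance requires 100 pA ≈ 1 µA/cm²,
and at 1 µA/cm² a halved-`g_na` cell cannot fire at all. We prioritised
the firing phenomenology, which is what the model exists to show. The
practical consequence is that the model's current axis is compressed
relative to experiment: "2× rheobase" in the model is a gentler relative
drive than "2× rheobase" at the rig.

When percentage changes in *spike height* are quoted, they are computed
on the height above the −70 mV reversal (the visual height of the spike
on a trace). The absolute peak voltage crosses 0 mV across the
conductance plane, and percentages of a quantity passing through zero
are meaningless.

### Numerics

Integration is forward Euler at `dt = 0.01` ms (an error is raised above
0.05 ms). Spike counts at `dt` and `dt/2` agree within one spike on the
default protocols, and the Euler trace agrees with a fourth-order
Runge–Kutta reference in the test suite. Two guards:

* α_m and α_n have removable singularities at −38 and −55 mV; within
  10⁻⁶ mV of those voltages the analytic limits (1.0 and 0.1 ms⁻¹) are
  used.
* Gates are clamped to [0, 1] after each step. The clamp only engages
  below ≈ −120 mV, where β_m is so large that τ_m < dt and the explicit
  update overshoots; the clamped value is the correct stiff limit. The
  −50 pA battery sweep reaches that range because of the high input
  resistance discussed above.

The initial state solves the steady-state current equation for the
resting potential by root bracketing (−100 to −40 mV); if no
subthreshold root exists the simulation falls back to −70 mV plus 500 ms
of silent equilibration. Noise, when on, is drawn per time step from
R's RNG (so traces are bit-reproducible given a seed) and injected at
every step, including the zero-current padding.

## The feature battery

Every definition follows the standard current-clamp conventions of the
source analysis. The ones with a genuine choice in them:

* **Spike detection** — threshold at the first sample of an upstroke
  with dV/dt ≥ 10 mV/ms (central differences, no sub-sample
  interpolation); a spike is valid if its amplitude (peak − threshold)
  is ≥ 40 mV and its peak overshoots −10 mV. Spike *times* are threshold
  crossings, not peaks.
* **Steady-state frequency** — valid spikes in the last 300 ms of a
  600 ms step / 0.3 s; the I–f curve records failures after cessation
  as 0. Instantaneous maximum = 1/min ISI at the step with the highest
  steady-state rate (falling back to the global minimum ISI).
* **Sag** — no formula is published; we use
  `100 (V_ss − V_min)/(V_baseline − V_min)` on the −50 pA sweep, which
  is zero for a passive RC membrane. The model has no h-current, so its
  sag is ~0: sag exists in the battery for real or differently
  synthesised data.
* **ISI CoV** — sample SD (n−1) over mean of the ISIs of one sweep; at
  the spike counts involved the population-SD variant differs
  negligibly. Fewer than 2 ISIs → `NA`.
* **AHP** — depth below threshold, searched from the peak to the next
  spike or 50 ms. **Time constant** — single-exponential fit of the
  hyperpolarizing onset, log-linear initialised. **Rundown** — spike
  amplitudes at 3× rheobase normalized to the first; with < 10 spikes
  the last ratio is reported and flagged partial.
* **Voltage clamp** — peak = max |I|; persistent = mean current
  80–100 ms post-step as % of peak; inactivation τ from a
  double-exponential-plus-offset fit (Levenberg–Marquardt), reporting
  the larger-amplitude component. Fit health is judged on residual
  size, not the optimizer's iteration flag.

## IS/CA classification

Two variables per cell, from one suprathreshold 8 s sweep: the initial
**burst length** (time of the last spike before the first firing gap
longer than the cutoff; trailing silence counts as a gap) and the
**ISI CoV**. The gap cutoff defaults to 150 ms, the published
dataset-derived value (mean + 2 SD of pooled ISIs); `gap_cutoff()`
re-derives it for any dataset, and on default synthetic cohorts gives
~190 ms. Cells are clustered with `stats::kmeans` (Lloyd's algorithm,
k = 2, 25 random restarts, fixed seed) after z-scoring both features —
without standardization the 0–8 s burst axis dwarfs the unitless CoV.
The cluster with the higher mean CoV is labelled IS. We use multiple
random restarts rather than k-means++ seeding: with k = 2 on
standardized, well-separated data every restart scheme finds the same
optimum, and `kmeans` is the canonical implementation. Cells with fewer
than 3 spikes (the near-silent *Scn1a* IS cells) cannot yield a CoV;
they are kept classifiable by imputing the cohort's 95th-percentile CoV
and flagged — near-silence is itself strong evidence of the IS/impaired
phenotype.

"Apparent" features computed from 600 ms sweeps use the same formulas
with `sweep_duration = 0.6` s. On synthetic cohorts they separate the
groups less cleanly than the 8 s features (lower silhouette), the
short-sweep limitation that motivates long depolarizations.

## The synthetic cohort

`generate_cohort()` draws four groups — WT/Scn1a × CA/IS — with
`g_na = 65 × scale × lognormal(1, cv = 0.1)` (scale 0.5 for *Scn1a*⁺/⁻,
i.e. loss of one gene copy) and `g_ks` from truncated normals:
CA ~ 0.25 ± 0.15, IS ~ 2.0 ± 0.4 mS/cm². The bimodal `g_ks` is the
generator's operationalization of "about half of VIP-INs carry enough
M-current to spike irregularly"; the overlap of its tails produces the
borderline cells that dominate the classifier's few-percent error rate,
which we consider a feature, not a bug — the underlying biology is a
continuum.

Each cell receives the recording battery: 1 s resting sweep, −50 pA
step, the ascending 600 ms family (0–200 pA by 10 pA; rheobase, I–f
curve, waveform features at rheobase), a 600 ms sweep at 3× rheobase
(rundown), and 8 s suprathreshold sweeps. The 8 s amplitude starts at
2× the cell's measured rheobase; if the sweep does not show a
measurable pattern — at least 10 valid spikes with firing persisting
into the last quarter — the amplitude escalates to 3× and 4× rheobase
(capped at 200 pA), and classification uses the first measurable sweep
(or, failing all, the one with the most spikes). This mirrors
experimental practice (patterns were confirmed at higher current
injections when unclear) and is required here because of the compressed
current axis noted above: halved-`g_na` cells sit in a single-spike
"dead zone" at 2× their measured rheobase and only reveal their
CA-vs-IS identity at higher drive. The escalation rule sees only the
cell's own response, never its generating label.

All randomness flows from the single cohort seed (per-cell seeds and
parameter draws derive from it), truth labels are stored apart from the
features to support blinded analysis, and traces are reduced to spike
trains and features on the fly — a full 8 s trace at 0.01 ms resolution
is ~13 MB, so whole-cohort raw traces are only kept on request.

What the generator does *not* emulate: synaptic background (noise is a
small injected current), h-current sag, the measured input-resistance
and rheobase scale, electrode artefacts, per-animal clustering, and
developmental age. Cohort ISI CoV medians keep the right ordering but
not the measured magnitudes: synthetic CA cells are nearly clockwork
(median ~0.01 vs the measured 0.30 — real cells sit in synaptic
background the model lacks) while synthetic IS cells are more irregular
than measured (~1.2 vs 0.61). Passing the cohort tests therefore
demonstrates that the pipeline recovers the structure this generator
produces, not that the model reproduces every moment of the real data.

Pharmacology is emulated at the conductance level:
linopirdine (KCNQ blocker) → `g_ks` × 0; retigabine (opener) →
`g_ks` × 2.5; carbachol (muscarinic) → `g_ks` × 0.1 plus a bias current
solved on the full steady-state I–V to depolarize rest by ≈ 12 mV.
Blocking M-current converts an IS model cell to continuous firing;
activating it makes a low-`g_ks` cell irregular — the bidirectional
switching seen with these drugs at the rig.

## Statistics

* `chi_square_2x2()` — Pearson χ² without continuity correction (the
  published statistic for the 51/63/41/31 genotype table, 2.63, is the
  uncorrected value; Yates' correction would give 2.17 and is available
  behind a flag).
* `mann_whitney_u()` — midrank U; exact two-sided p (doubled smaller
  tail, capped at 1) by complete enumeration when `choose(n+m, n)` ≤
  2×10⁵ (handles ties), by the exact Wilcoxon distribution for tie-free
  samples with `n·m` ≤ 400, else the tie-corrected normal
  approximation. Literal enumeration at, say, n = m = 20 would need
  ~10¹¹ subsets; the exact distribution is mathematically identical
  there.
* `vertical_bias()` — length-weighted fraction of dendrite within 30°
  of vertical, angles per polyline segment, folded to [0°, 90°];
  1 for bipolar, ~1/3 for isotropic arbors.
* `group_summary()` — mean ± SEM per group, optionally aggregating each
  animal to one value first.

## Problem sizes and known limitations

The test suite runs cohorts of 4–50 cells per group and single sweeps of
0.6–8 s; the acceptance script regenerates a 50-cell-per-group cohort
end to end. Known limitations, beyond the calibration trade-off above:
the model is type II near threshold (abrupt firing onset, low rheobase),
so near-rheobase behaviour should not be over-interpreted; CoV
magnitudes are generator-specific; real-data group means (firing rates,
AP waveform values) are not reproducible from simulation and are only
matched in ordering and effect direction; and the Mann–Whitney
"not significant" contrasts seen in small real samples need the real
within-group variance, which the generator does not attempt to match.
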