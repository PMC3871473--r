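---
title: "Methods: beat-by-beat cardiac energy transfer and its agreement analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beat-by-beat cardiac energy transfer and its agreement analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cardiac power output (CPO = mean arterial pressure × cardiac output) summarizes
the *mean* hydraulic power the left ventricle delivers to the circulation, but
it is available only as a multi-beat average. The instantaneous cardiac power
curve, PWR(t) = p~ao~(t)·q~ao~(t), can be integrated over one cardiac cycle to
give the *total* hydraulic energy delivered to the proximal aorta per beat (in
Joules) — mean plus oscillatory power. The reference measure of per-beat
ventricular energy is stroke work (SW), the area enclosed by the left
ventricular pressure–volume loop. `cardiopower` implements both measures, the
conductance-catheter calibration that SW depends on, and the statistical
machinery for asking whether the PWR integral tracks SW beat by beat across
loading and contractility interventions.

Because no public recordings of this kind exist, the package also ships a
physiologically explicit generator, so every stage of the pipeline is testable
against known ground truth.

## Beat metrics

**Cycle convention.** Cycles run from one ECG R peak to the next, half-open
`[R_k, R_{k+1})`, 1-based sample indices. Detection is threshold +
local-maximum with a 200 ms refractory period. One boundary case is worth
stating: a record of *n* complete cycles carries *n* onset spikes, so the span
after the last peak would be lost under a strict peak-pair rule. The record
end is therefore treated as a bracketing boundary — a trailing span is emitted
when the remaining tail is within 2% of the median RR interval; genuinely
partial tails are discarded.

**Integrals.** Per-cycle quantities use the trapezoidal rule at the record's
sampling rate (1 kHz by default), including the closing sample of each span,
so a constant integrand over a 1.000 s span integrates to exactly its value
times one second. At 1 kHz the quadrature scheme is immaterial to ~10⁻⁴
relative; it is fixed for bit-reproducibility. The PWR series is *not* floored
at zero: small negative diastolic flow (Windkessel recoil) integrates as
measured.

**Stroke work** is the absolute shoelace area of the (V, P) polygon over one
cycle, in SI units, which makes it invariant to traversal direction and to the
starting sample within the cycle.

**Units.** Channels live in clinical units (mmHg, L/min, mL) on disk and in
records; every energy computation converts to SI first (mmHg → Pa ×133.322,
L/min → m³/s ÷60000, mL → m³ ×10⁻⁶), so energies are Joules and powers Watts
with no hidden constants.

**Alpha calibration.** Conductance-catheter volume has a gain error; the
per-animal calibration factor is

α = mean(SV~conductance~) / mean(SV~flow-probe~),

computed once per animal from baseline cycles only, and the calibrated volume
is v/α. The correction is gain-only by design: loop area is invariant to a
volume offset, so no offset term is identifiable from SW — or needed.
Two numerical facts matter here:

* With channel noise, SV~conductance~ = max − min of the measured volume is
  biased upward (extremes of a noisy series), inflating α by a few percent at
  the default 0.5 mL noise SD. This is a faithful property of the measurement
  convention, not a bug; it cancels out of within-animal agreement statistics
  almost entirely.
* Noise-free, the flow-probe SV (trapezoid integral of q~ao~) and the
  conductance SV disagree by ~10⁻⁵ relative at 1 kHz, purely from quadrature
  error at the valve-opening kink of the flow waveform; the error falls as
  fs⁻² and is ~10⁻⁷ at 10 kHz. Exactness claims about the calibration
  estimator are therefore made at 10 kHz, and 10⁻⁴-level agreement at the
  1 kHz instrument rate.

**Oscillatory fraction.** Total power is the cycle-averaged PWR integral per
unit time; steady power is MAP × mean flow computed with the *same*
trapezoid-weighted time averages, so a constant pressure yields exactly zero
oscillatory power. The fraction is clipped at zero for numerically tiny
negatives.

**Alignment.** Pressure and flow are taken as synchronous: in the porcine
preparation the probe-to-manometer distance is short enough that propagation
delay is negligible. No alignment shift is applied by default.

## The synthetic preparation

The generator is the minimal lumped model that reproduces the experimental
morphology — near-zero diastolic aortic flow, systole-dominated power: a
time-varying-elastance left ventricle, p~lv~ = E(t)(V − V₀), coupled through
an aortic valve resistance to a 3-element Windkessel (characteristic
resistance R~c~, compliance C~a~, peripheral resistance R~p~), filled from a
constant venous pressure through a mitral resistance. E(t) interpolates
between E~min~ and E~max~ with a double-cosine activation (rise to the peak at
60% of systole, fall back to E~min~ at 40% of the cycle). The two states (LV
volume, Windkessel pressure) are integrated with fixed-step RK4 at the
sampling rate; 15 warm-up cycles are discarded, after which per-cycle stroke
volume varies by <1% (the arterial time constant R~p~C~a~ ≈ 2.4 s is well
inside that warm-up). The ECG channel is a synthetic 5-sample triangular spike
at each cycle onset — the experiment records ECG only to delimit cycles.

Species defaults describe a 25–30 kg anesthetized pig: HR 90 min⁻¹, E~max~
3.5 mmHg/mL, E~min~ 0.13 mmHg/mL, V₀ 5 mL, R~valve~ 0.010, R~c~ 0.035, R~p~
1.2 mmHg·s/mL, C~a~ 2.0 mL/mmHg, venous pressure 8 mmHg. These were fixed by
a single calibration pass (then frozen) against four *a priori* constraints:
CO ≈ 3–3.5 L/min, MAP ≈ 75–80 mmHg, diastolic aortic flow < 5% of peak, and
an oscillatory power fraction near the textbook ~15%. Splitting the series
resistance in favour of the valve (upstream of the pressure-measurement site)
rather than the characteristic resistance is what keeps the flow-weighted
aortic pressure close to MAP and hence the oscillatory fraction near 15%.

**Conditions.** The six interventions are parameter multipliers: preload
reduction halves venous pressure (caval banding; cuts CO by ~50%, comfortably
beyond the protocol's ≥20% requirement); afterload increase scales R~p~ ×1.6;
dobutamine scales E~max~ ×1.5, HR ×1.15, R~p~ ×0.9; nitroprusside scales R~p~
×0.65 and venous pressure ×0.85; metoprolol scales E~max~ ×0.7 and HR ×0.85.
Directions follow each drug's known pharmacology; magnitudes are chosen to
give clearly separated hemodynamic states, not fitted to any data.

**Measurement model.** The conductance volume channel is reported as
α~true~·V + offset (α~true~ uniform on [0.85, 1.35] per animal, offset
[−5, 15] mL), and every channel receives additive Gaussian noise (defaults:
0.5 mmHg on pressures, 0.05 L/min on flow, 0.5 mL on volume, 0.02 a.u. on
ECG — representative of well-calibrated clinical instruments). Between-animal
variation is seeded lognormal jitter (SD 10%) on rate, elastances, tone and
filling; between-measurement drift is the same jitter at SD 3% on E~max~,
venous pressure and R~p~, standing in for the stabilization periods between
recordings. All randomness derives from one top-level seed.

**What the generator does not emulate:** respiratory modulation (the ventilator
was disconnected during real measurements), baroreflexes (pharmacologically
blocked in the preparation), pulmonary circulation, wave reflection and
propagation delay, conductance-catheter field inhomogeneity, and the specific
Table-level coefficients of any real animal. A green test therefore
establishes the *machinery* — segmentation, integration, calibration,
statistics — and the qualitative physiology, not the numerical coefficients
of the in-vivo study. Mitral regurgitation is available qualitatively
(`regurg_frac`) and reproduces the expected pattern — SW inflates relative to
the PWR integral as regurgitant volume grows — without claiming to match any
particular animal's episode.

## Agreement statistics

**Through-origin regression.** Zero SW must give zero PWR integral, so
per-animal fits are constrained through the origin: slope Σxy/Σx² with a
naive OLS standard error on n−1 df. "Correlation without a constant" is
reported as the uncentered R² = (Σxy)²/(Σx²Σy²) of that fit; the conventional
centered Pearson r is also reported, labelled separately, since the two differ
conceptually. Beats within a measurement are treated as independent, as the
original analysis did; the printed CIs inherit that assumption.

**Direction.** The default regresses the PWR integral on SW, so slopes above
1 mean the PWR integral runs consistently above SW (as expected: SW excludes
the filling energy, which exceeds the small valve/characteristic losses the
PWR integral misses). The direction is a switch, because figure axes and
table labels can legitimately differ.

**Bland–Altman.** Differences are SW − PWR integral, plotted against the pair
mean; limits of agreement are mean ± 1.96 SD (n−1 denominator).

**Mixed model.** Pooled across animals, the model is

y~ij~ = (β~c(ij)~ + b~i~)·x~ij~ + ε~ij~, b~i~ ~ N(0, τ²), ε ~ N(0, σ²),

with no intercept in either the fixed or random part: a per-condition fixed
slope and a per-animal random slope deviation. Because the random structure is
a single scalar slope, each animal's covariance is the rank-one matrix
σ²(I + λx~i~x~i~ᵀ) with λ = τ²/σ², and the restricted likelihood profiles to a
1-D optimization over λ via the Woodbury identity — no general mixed-model
machinery needed, and the fit is deterministic. REML is the default (ML by
flag). Condition slopes are compared to the reference by Wald z-tests; τ² = 0
is tested by a likelihood-ratio test with the usual boundary halving of the
p-value. The implementation is cross-checked against `lme4` on identical data
in the test suite (agreement to 10⁻⁴ on the fixed slopes), and its Wald
p-values are verified to be uniform under the null by simulation.

Degenerate inputs are handled explicitly: a perfect (zero-residual) fit
returns the exact pooled slope with τ² = 0 and LRT p = 0.5; a single animal is
refused (τ² inestimable); an optimum pinned at the λ upper bound is flagged
as non-converged, never silently accepted.

## The in-silico protocol

The default protocol mirrors the experimental design: per animal, 10 sets of
(baseline, reduced preload, increased afterload) — mechanical interventions
first, so no drug carry-over — then 10 measurements each under dobutamine,
nitroprusside and metoprolol; 10 cycles per measurement. That is 60
measurements and 600 SW/PWR-integral pairs per animal, 3600 for the default
6-animal cohort. `analyze_dataset()` chains detection → segmentation → alpha
calibration (baseline only) → beat summary → per-animal fits and Bland–Altman
→ the pooled mixed model, and writes the per-animal, per-condition and
Bland–Altman tables plus a run log. Nothing is auto-excluded; exclusion
counts in the log exist so a human can audit them.

## Numerical choices, in one place

* RK4, fixed step at fs; no adaptive stepping, hence bit-reproducible runs.
* Trapezoid for all time integrals; shoelace for loop areas.
* Warm-up 15 cycles; steady-state SV drift < 1% enforced by test.
* Seeds: one integer per entry point; per-measurement seeds are drawn from
  the top-level seed; the measurement model is bit-identical under a fixed
  seed.
* Tolerances asserted in tests: closed-form integral oracles 10⁻⁴, polygon
  oracles 10⁻³, per-cycle energy balance 1%, alpha recovery 10⁻⁶ (noise-free,
  10 kHz), through-origin slope vs grid search 10⁻⁶, mixed model vs `lme4`
  10⁻⁴ on slopes.

## Known limitations

The slopes and their spread across synthetic animals arise from the model's
filling-energy/valve-loss physics plus parameter jitter; they land in a
narrower band (~1.04–1.12) than the range reported for real animals
(0.95–1.33), which also reflects instrument drift and anatomy the generator
does not model. The mixed model treats beats as exchangeable within animal ×
condition; no serial correlation structure is offered. The CLI's JSON config
covers protocol-level knobs only; per-animal parameter overrides are an API
affair.
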