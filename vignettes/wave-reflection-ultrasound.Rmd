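---
title: "Wave-reflection carotid ultrasound: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wave-reflection carotid ultrasound: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the hemodynamic model behind the synthetic data, the measurement
conventions used at every stage of the analysis chain, the places where
the method is genuinely under-determined and the conventions we chose,
and what the simulation-based tests do and do not demonstrate about real
recordings.

## 1. The linear-wave model behind the generator

In a compliant artery, a pressure/flow pulse travels at the local pulse
wave velocity `c`. For a forward-running wave, flow and lumen-area
perturbations are locked together, `q_f = c · a_f` (SI units:
m³/s, m², m/s); for a backward-running (reflected) wave the sign flips,
`q_r = −c · a_r`. The generator builds one recording as:

* a **forward pulse** `q_f(t)`: raised-cosine upstroke of duration
  `tRise` followed by an exponential decay with time constant `tDecay`,
  on a diastolic baseline `Q_dia`. This shape is smooth, has a single
  systolic peak inside the first 40% of the cycle, and is
  periodically extended over cycles (the recording is assumed to start
  in steady state, so delayed terms wrap into the previous cycle);
* a **reflection** `Q_r(t) = −γ · q_f(t − τ)`: a scaled, delayed copy
  that *opposes* net flow while its area perturbation *adds*,
  so `A(t) = A_dia + (q_f(t) + γ q_f(t − τ))/c`. This sign convention is
  what makes a reflected wave raise area per unit flow, and is the whole
  basis of the flow-area method;
* net flow `Q = Q_f + Q_r` (machine-exact before noise), velocity
  `V = Q/A`, and additive Gaussian noise applied after construction,
  scaled as a fraction (`noiseSd`, default 0.02) of each signal's
  peak-to-peak range.

Default parameters describe a healthy adult mouse common carotid under
light anesthesia: `c = 3` m/s, `γ = 0.3`, `τ = 30` ms, diastolic
diameter 0.45 mm, wall thickness 0.05 mm, heart rate 450 beats/min,
diastolic flow 0.35 mL/min with a 1.4 mL/min pulse (cycle-mean flow
≈ 0.8 mL/min), blood density 1.05 g/mL. With `γ = 0` the model
degenerates to exact flow-area proportionality — the reflection-free
limit every estimator is tested against.

Optional rhythm pathology: per-cycle RR jitter drawn from a scaled
Student-t with 3 df (heavy-tailed), and with probability `arrProb` a
beat is prolonged by `arrScale` (default 1.6×) — enough to trip the 20%
RR rejection rule downstream, as arrhythmic beats do in diseased
animals.

## 2. Image rendering and what it does (not) emulate

The M-mode renderer draws two bright bands at depths
`centerDepth ∓ D(t)/2`, each with a Gaussian depth profile whose FWHM
equals the wall thickness, over a dim background; the Doppler renderer
fills velocity bins from zero up to `V_max(t) = 2·V(t)` (parabolic
profile convention — the inverse of the analysis-side halving rule),
partially filling the edge bin in proportion to coverage. Noise is
multiplicative unit-mean Rayleigh speckle (level 0–1, default 0.5,
i.e. halfway to fully developed speckle) plus, for Doppler, an additive
half-normal noise floor.

This emulates the *geometry and statistics* that the extraction stage
must cope with — band motion, band width, speckle, envelope
quantization, noise above the envelope — not ultrasound physics. There
is no beam model, no attenuation or shadowing, no intima/media layering
(the band-center-to-band-center distance is declared to be the lumen
diameter; a real instrument's "outline" may track a different acoustic
interface), no ECG channel, and no angle-of-insonation error (treated
as already corrected at acquisition). Passing round-trip tests therefore
shows that the *algorithms* are correct at their stated tolerances, not
that the pipeline is robust to every artifact of real scans.

## 3. Extraction conventions

* **Walls**: per scan line, the depth profile is smoothed with a
  Gaussian (σ = 2 px — approximately a matched filter, since the
  rendered band σ is ≈ 2 px at the default pitch) and the two highest
  local maxima separated by ≥ 0.15 mm are taken. Centers are refined by
  parabolic interpolation (≈ 0.03 px noiseless accuracy); thickness is
  the FWHM with the smoothing kernel removed in quadrature. Lines where
  two bands cannot be found are interpolated; if they exceed 10% of the
  trace, extraction fails loudly. A width-3 temporal median rejects
  single-line dropouts.
* **Envelope**: the threshold is the 95th percentile of the noise floor,
  estimated from the top decile of velocity bins (above any
  physiological velocity). The envelope bin is the top of the highest
  run of three supra-threshold bins — an isolated noise excursion is
  not a run — and the position within that bin is refined by its
  (clamped) intensity, which at zero noise equals the fill fraction
  exactly. Raising the threshold can only lower the envelope
  (monotone), and the mean velocity is the envelope halved.

## 4. Cycle segmentation and averaging

The start of systole is found on the velocity signal by the
intersecting-tangents convention: the horizontal tangent through the
pre-upstroke minimum intersected with the tangent at maximum upstroke
slope. Before differentiation the signal is Gaussian-smoothed (σ = 2 ms)
with reflective padding; the reference slope is the 99.5th percentile of
the derivative rather than its maximum, so one glitch cannot mask every
upstroke. Feet are detected once and reused for all signals, keeping
area, velocity and derived signals phase-locked. Cycles whose RR
deviates from the median by more than 20% are rejected and logged; each
retained cycle is linearly resampled to N = 256 samples (power of two,
convenient for harmonic analysis) and averaged pointwise. The final
partial cycle is always discarded. Heart rate is 60 over the median
retained RR.

## 5. Metric conventions and numerical choices

* **QA loop**: the fit window is the *ascending limb only* (foot to
  peak flow), and the 20–80% band is measured above the foot flow, not
  above zero — the upstroke is the reflection-free interval the method
  relies on. Ordinary least squares of `Q` on `A` in SI units gives the
  slope directly in m/s; R², window indices and a negative-slope flag
  are always reported. Fewer than 4 samples in the window is an error.
* **Harmonic smoothing**: before metric computation, the mean area and
  velocity cycles are low-passed by harmonic truncation (first 25
  heart-rate harmonics kept). Being linear, this preserves the
  reflection-free proportionality exactly and leaves the first harmonic
  (hence the reflection coefficient) untouched, while suppressing
  extraction noise that would otherwise attenuate the OLS slope
  (errors-in-variables dilution).
* **Wave separation** uses end-diastolic (foot) baselines. The method
  requires *some* baseline; the foot is the only unambiguous landmark
  of a foot-aligned mean cycle, so `Q_dia = Q[1]`, `A_dia = A[1]`.
  `Q_f + Q_r = Q` holds exactly by construction on every input.
* **Reflection coefficient**: the mean cycle is treated as exactly one
  period, with no windowing; RC is |reflected/forward| at the first
  harmonic. The ratio's orientation is genuinely ambiguous in the
  field's phrasing; reflected-over-forward is implemented (bounded by 1
  for sub-total reflections, directly interpretable), and the
  reciprocal is kept in the diagnostics.
* **Diameter** is the end-diastolic diameter of the mean cycle (foot
  sample), chosen to pair with the end-diastolic area used as the wave
  separation baseline. **Flow** is the instantaneous product
  `A(t)·V(t)` (not mean-area × velocity), averaged over the cycle.
* **Moens–Korteweg** uses the thin-wall form with the *lumen* (inner,
  end-diastolic) diameter and ρ = 1.05 g/mL: `E = c²ρD/h`, reported in
  kPa. Both conventions (lumen vs mid-wall diameter; thin wall) matter
  at the ~10% level and are stated here so results are comparable.

## 6. Cohort simulation

The cohort simulator plants known multiplicative effects at the metric
level: per-metric baselines (control female LCCA at the first age), a
male/female ratio, an RCCA/LCCA asymmetry (right larger in diameter and
flow), a control age trend (flow and diameter grow with age), and a
genotype effect table per (metric, sex, age) mirroring the phenotype the
package models — males: +12% diameter and −22…−30% PWV from the first
age; females: −25% flow and −29% heart rate at the first age reversing
later, with late +15% diameter, +21% PWV, +25% reflection coefficient
and +28% elastic modulus. Between-mouse heterogeneity and scan-to-scan
residual noise are log-normal with per-metric SDs of 3–15% — the range
of published small-animal ultrasound repeatability, tighter for
geometry than for flow-derived quantities. A third of mutant males drop
out before the final age, producing the missingness the mixed models
must tolerate.

Each simulated (mouse, age, side) row also yields a waveform-level truth
(wave speed from the row's PWV, geometry from its diameter and wall
thickness, reflection magnitude from its RC, pulse scaled to its flow),
so the same cohort can be pushed through the full image chain.
Pulsatility index and Young's modulus are not plantable at waveform
level — they emerge from the pulse shape and the Moens–Korteweg
relation — so full-chain runs recover genotype effects only for the
directly planted quantities.

## 7. Statistics

The longitudinal model is
`metric ~ genotype + age + sex + side (+ interactions) + (1 | mouse)`,
fitted by REML (lme4). Age is categorical by default (three imaging
ages; a continuous option exists behind a flag). Fixed-effect p-values
use the **Wald normal approximation**: with 24 mice this is mildly
anti-conservative (the null simulation shows a rejection rate of ~5–7%
at nominal 5%), and we prefer making that visible through the
calibration simulation to hiding it behind a degrees-of-freedom recipe.
Post-hoc simple effects are obtained by releveling — a pure
reparameterization, verified by log-likelihood invariance. The
pre-onset screen tests each metric's genotype simple effect within each
sex at the earliest age (releveled from the full model by default; a
stratified per-sex refit is available), with **no multiplicity
correction** by default, matching the analysis style it reproduces; a
Benjamini–Hochberg option exists behind a flag. Significant metrics get
an empirical ROC (pROC; thresholds are midpoints plus ±∞, AUC is the
Mann–Whitney statistic) with the Youden-optimal cut-off, ties broken
toward the lower threshold and orientation chosen so AUC ≥ 0.5.

## 8. Problem sizes and determinism

The test suite and acceptance script run the noiseless recovery grids
(wave speeds 2–6 m/s × reflection magnitudes 0–0.45) on 8-cycle
recordings at 5 kHz; the noise study uses 100 seeds; mixed-model
calibration uses 200–500 simulated cohorts of 24 mice; and the demo
study is the full design (6 mice/genotype/sex, 3 ages, both sides,
~2.7 s recordings at a 1 kHz line rate) through image rendering and
extraction — sizes chosen so the whole battery completes in a few
minutes on one CPU while keeping every Monte-Carlo margin comfortable.
Every stochastic step takes an explicit seed; a pipeline run with the
same configuration and seed reproduces its metric CSVs byte for byte.

## 9. Known limitations

* The QA-loop method assumes a reflection-free early upstroke; when the
  reflection delay is short relative to the rise time (strong, proximal
  reflectors), the slope is biased and the grid tests quantify that
  bias (≈ 2% at the default delay, growing as τ shrinks).
* Measured full-chain PWV carries ~10% per-recording noise at the
  default speckle level — comparable to published repeatability of the
  technique — so single recordings should not be over-interpreted;
  group contrasts are the intended use.
* No pressure is measured or simulated; wave *intensity* analysis and
  pressure-based separation are out of scope, as is any viscoelastic
  wall model.
* The two-band M-mode appearance is a modeling convention, not a claim
  about any particular instrument; absolute wall-thickness accuracy
  depends on which acoustic interfaces a real scanner highlights.
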