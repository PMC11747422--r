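# carotidwave

Carotid ultrasound waveform analysis and wave-reflection hemodynamics for
mouse studies, with a fully ground-truthed synthetic-data generator.

## The problem

High-frequency ultrasound of the common carotid arteries gives a
non-invasive window on the cerebral circulation of the mouse: vessel
geometry (M-mode wall motion), blood velocity (pulsed Doppler), and —
through wave analysis — arterial stiffness and downstream vascular
resistance. In longitudinal studies of neurodegeneration models these
quantities are candidate *early biomarkers*: changes in carotid blood
flow, diameter and pulse wave velocity can precede any behavioral or
histological sign of disease, and they do so in a sex-specific way.

`carotidwave` implements the complete measurement chain for such studies,
for people who want to analyse carotid M-mode/Doppler recordings, to
verify a wave-reflection analysis stack against known ground truth, or to
power/design longitudinal imaging experiments by simulation:

1. **synthwave** — generates flow/area/velocity waveforms from a
   linear-wave model with a planted reflection, renders them as M-mode
   images and Doppler spectrograms, and simulates longitudinal cohorts
   (genotype × sex × age × side) with known multiplicative effects.
2. **trace extraction** — outlines the two wall bands in an M-mode image
   (sub-pixel band centers, FWHM wall thickness) and traces the Doppler
   maximum-velocity envelope (mean velocity = envelope/2).
3. **cycle processing** — detects the start of systole by intersecting
   tangents, rejects arrhythmic cycles (RR deviating > 20% from the
   median), resamples each cycle to 256 samples and ensemble-averages.
4. **hemodynamics** — on the mean cycle: flow `Q = A·V`; pulse wave
   velocity from the QA loop (OLS slope of `Q` on `A` over the 20–80%
   band of the systolic upstroke); wave separation
   `Q_f = Q_dia + (q + c·a)/2`, `Q_r = (q − c·a)/2` about the
   end-diastolic baselines; reflection coefficient
   `RC = |H₁(Q_r)|/|H₁(Q_f)|` at the heart-rate harmonic; pulsatility
   index `(V_peak − V_ED)/V_mean`; Young's modulus from Moens–Korteweg
   `E = c²·ρ·D/h` with blood density 1.05 g/mL.
5. **cohort stats** — linear mixed-effects models
   (`metric ~ genotype + age + sex + side + interactions + (1|mouse)`,
   REML via lme4, Wald-normal p-values), post-hoc simple effects by
   releveling, and ROC/AUC with Youden cut-offs (pROC) for the pre-onset
   biomarker screen.
6. **pipeline** — `runPipeline()` orchestrates
   simulate → render/extract → cycle → metrics → stats with a manifest,
   per-stage seeds and byte-identical reruns; `makeFigures()` draws the
   longitudinal mean±SEM panels and the `Q = Q_f + Q_r` decomposition
   overlay. A thin CLI lives in `inst/scripts/carotidwave`.

## Worked example

```r
library(carotidwave)

truth <- hemoTruth(cTrue = 3, gammaTrue = 0.3, seed = 42)
truth
#> HemoTruth: c = 3 m/s, gamma = 0.3 , tau = 0.03 s
#>   D_dia = 0.45 mm (A_dia = 0.15904 mm^2), h = 0.05 mm, HR = 450 bpm
#>   pulse: Q_dia = 0.35 mL/min, amplitude = 1.4 mL/min, rise 0.025 s, decay 0.03 s
#>   rho = 1.05 g/mL, noise = 0.02 , RR jitter = 0 , P(arrhythmia) = 0

wf <- synthesizeWaveforms(truth, nCycles = 8)
t <- wf@t; area <- wf@A * 1e6; vel <- wf@V * 1e3   # SI -> mm^2, mm/s

feet <- detectSystoleFeet(t, vel)
ens <- ensembleAverage(t, list(area = area, velocity = vel), feet)
ens
#> CycleEnsemble: 7 cycles used, 0 rejected; 256 samples/cycle
#>   period 0.1333 s; heart rate 450.1 bpm; signals: area, velocity

computeVesselMetrics(ens, wallThickness = truth@hTrue)
#> VesselMetrics
#>   diameter 0.451 mm; wall 0.05 mm; flow 0.6557 mL/min; HR 450.1 bpm
#>   PI 1.897 ; PWV 3.044 m/s; RC 0.3012 ; E 87.75 kPa
```

The planted wave speed (3 m/s) and reflection magnitude (0.3) are
recovered as 3.04 m/s and 0.301 from the noisy waveforms; mean flow,
diameter and heart rate match the generator's parameters.

A full in-silico study (6 mice/genotype/sex, ages 50/75/125 days, both
carotids, image rendering and extraction included) runs in about a
minute:

```r
mf <- runPipeline(defaultRunConfig(seed = 7), outdir = "demo_run")
read.csv(file.path("demo_run", "screening_report.csv"))
makeFigures(mf)
```

The day-50 screen on that run flags the planted sex-specific early
biomarkers — lower blood flow in female mutants, larger diameter and
lower PWV in males — each with its AUC and Youden cut-off.

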