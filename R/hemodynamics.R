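# Derived hemodynamic metrics from the ensemble-averaged cycle: flow,
# QA-loop pulse wave velocity, forward/reflected wave separation,
# reflection coefficient, pulsatility index, Moens-Korteweg elasticity.

#' Lumen area from diameter (circular cross-section)
#' @param d diameter (any length unit).
#' @return Area `pi d^2 / 4` in the squared unit.
#' @examples areaFromDiameter(0.5)  # 0.19635 mm^2 for d in mm
#' @export
areaFromDiameter <- function(d) pi * d^2 / 4

#' Diameter from lumen area (circular cross-section)
#' @param a area.
#' @return `sqrt(4 a / pi)`.
#' @export
diameterFromArea <- function(a) sqrt(4 * a / pi)

#' Flow waveform from area and velocity
#'
#' Instantaneous product `Q(t) = A(t) V(t)` per sample, converted from
#' mm^2 times mm/s (= mm^3/s) to mL/min (factor 0.06).
#'
#' @param area_mm2 area waveform, mm^2.
#' @param v_mms mean-velocity waveform, mm/s.
#' @return list: `Q_ml_min` (waveform) and `meanFlow` (cycle average,
#'   mL/min).
#' @export
flowWaveform <- function(area_mm2, v_mms) {
  stopifnot(length(area_mm2) == length(v_mms))
  Q <- area_mm2 * v_mms * 0.06
  list(Q_ml_min = Q, meanFlow = mean(Q))
}

#' QA-loop pulse wave velocity
#'
#' Plots flow against area over the systolic upstroke of the mean cycle
#' and fits a line to the samples where flow lies between `lower` and
#' `upper` (default 20% and 80%) of the peak-to-foot flow excursion,
#' measured above the foot flow. During this reflection-free early
#' systolic interval the slope dQ/dA equals the local pulse wave velocity.
#'
#' @param Q_ml_min mean-cycle flow, mL/min (cycle starting at the foot).
#' @param A_mm2 mean-cycle area, mm^2, sample-aligned with the flow.
#' @param lower,upper fractions of the systolic flow excursion bounding
#'   the fit window.
#' @return list: `pwv` (m/s), `r2`, `window` (sample index range used),
#'   `n` (samples in window), `negativeSlope` flag. Fails if fewer than 4
#'   samples fall in the window; a negative slope is flagged but the value
#'   is still reported.
#' @export
pwvQALoop <- function(Q_ml_min, A_mm2, lower = 0.2, upper = 0.8) {
  stopifnot(length(Q_ml_min) == length(A_mm2))
  ipk <- which.max(Q_ml_min)
  ift <- which.min(Q_ml_min[seq_len(ipk)])
  qFoot <- Q_ml_min[ift]; qPk <- Q_ml_min[ipk]
  if (qPk <= qFoot) stop("QA fit failed: no systolic upstroke in the flow")
  lo <- qFoot + lower * (qPk - qFoot)
  hi <- qFoot + upper * (qPk - qFoot)
  sel <- seq(ift, ipk)
  sel <- sel[Q_ml_min[sel] >= lo & Q_ml_min[sel] <= hi]
  if (length(sel) < 4)
    stop(sprintf("QA fit failed: only %d samples in the 20-80%% window",
                 length(sel)))
  fit <- lm(q ~ a, data = data.frame(q = mlMinToM3s(Q_ml_min[sel]),
                                     a = mm2ToM2(A_mm2[sel])))
  slope <- unname(coef(fit)[2])
  r2 <- summary(fit)$r.squared
  list(pwv = slope, r2 = r2, window = range(sel), n = length(sel),
       negativeSlope = slope < 0)
}

#' Separate a waveform into forward and reflected components
#'
#' Linear wave separation about the end-diastolic (foot) baselines: with
#' perturbations `q = Q - Q_dia` and `a = A - A_dia` and wave speed `c`,
#' the forward and reflected flows are
#' `Q_f = Q_dia + (q + c a) / 2` and `Q_r = (q - c a) / 2`.
#' By construction `Q_f + Q_r = Q` at every sample. A forward-running wave
#' raises flow and area together (`q = c a`), a reflected wave raises area
#' while opposing flow, which is what makes the decomposition identify it.
#'
#' @param Q_ml_min flow waveform, mL/min.
#' @param A_mm2 area waveform, mm^2.
#' @param pwv wave speed from [pwvQALoop()], m/s.
#' @param qDia,aDia baselines; default the first sample (the cycle foot).
#' @return list: `Qf_ml_min`, `Qr_ml_min`.
#' @export
decomposeWaves <- function(Q_ml_min, A_mm2, pwv, qDia = Q_ml_min[1],
                           aDia = A_mm2[1]) {
  stopifnot(length(Q_ml_min) == length(A_mm2), is.finite(pwv))
  cf <- pwvToFieldSlope(pwv)  # (mL/min) per mm^2
  q <- Q_ml_min - qDia
  a <- A_mm2 - aDia
  list(Qf_ml_min = qDia + (q + cf * a) / 2,
       Qr_ml_min = (q - cf * a) / 2)
}

#' First-harmonic reflection coefficient
#'
#' The mean cycle is treated as exactly one period (the fundamental is the
#' heart rate) and no windowing is applied. The reflection coefficient is
#' the magnitude of the ratio of the first discrete Fourier harmonics of
#' the reflected and forward waveforms: `RC = |H1(Qr)| / |H1(Qf)|`. The
#' phrase "ratio of the first harmonics" does not fix an order; the
#' bounded, interpretable reflected-over-forward orientation is used, and
#' the reciprocal is returned as a diagnostic.
#'
#' @param Qf,Qr forward and reflected mean-cycle waveforms (one period).
#' @param tol relative tolerance below which the forward first harmonic is
#'   considered degenerate (error).
#' @return list: `rc`, `h1Forward`, `h1Reflected` (complex), `reciprocal`.
#' @export
reflectionCoefficient <- function(Qf, Qr, tol = 1e-10) {
  stopifnot(length(Qf) == length(Qr), length(Qf) >= 4)
  Hf <- fft(Qf)[2]
  Hr <- fft(Qr)[2]
  scale <- max(Mod(fft(Qf)))
  if (Mod(Hf) <= tol * max(scale, 1e-300))
    stop("reflection coefficient undefined: forward first harmonic is zero")
  list(rc = Mod(Hr) / Mod(Hf), h1Forward = Hf, h1Reflected = Hr,
       reciprocal = if (Mod(Hr) > 0) Mod(Hf) / Mod(Hr) else Inf)
}

#' Pulsatility index
#'
#' `PI = (V_peak - V_ED) / V_mean`: peak systolic minus end-diastolic
#' velocity, divided by the cycle-mean velocity. The end-diastolic
#' velocity is the value at the cycle foot (the first sample of a
#' foot-aligned mean cycle).
#'
#' @param v velocity mean cycle (any unit; PI is dimensionless).
#' @param footIndex index of the cycle foot.
#' @return PI (dimensionless).
#' @examples
#' # V_peak 60, V_ED 10, V_mean 25 (mm/s) -> PI = 2
#' pulsatilityIndex(c(10, 60, 35, 30, 25, 20, 10, 10))
#' @export
pulsatilityIndex <- function(v, footIndex = 1L) {
  (max(v) - v[footIndex]) / mean(v)
}

#' Moens-Korteweg Young's modulus
#'
#' Thin-wall Moens-Korteweg relation `c = sqrt(E h / (rho D))` rearranged
#' for the elastic modulus: `E = c^2 rho D / h`, with the inner
#' (end-diastolic lumen) diameter convention. Blood density defaults to
#' 1.05 g/mL (1050 kg/m^3).
#'
#' @param pwv pulse wave velocity, m/s.
#' @param dDia_mm end-diastolic inner diameter, mm.
#' @param h_mm wall thickness, mm (same unit as the diameter; only the
#'   ratio enters).
#' @param rho blood density, kg/m^3.
#' @return Young's modulus, kPa.
#' @examples youngsModulus(3, 0.5, 0.05)  # 94.5 kPa
#' @export
youngsModulus <- function(pwv, dDia_mm, h_mm, rho = 1050) {
  stopifnot(h_mm > 0, dDia_mm > 0, rho > 0)
  pwv^2 * rho * (dDia_mm / h_mm) / 1000
}

#' Harmonic truncation low-pass for one periodic cycle
#'
#' Keeps the DC component and the first `nHarm` harmonics of a signal
#' treated as exactly one period. Extraction noise (speckle) is white
#' while the hemodynamic waveforms live in the first few dozen heart-rate
#' harmonics, so truncation suppresses noise without phase distortion;
#' being linear, it preserves the reflection-free flow-area
#' proportionality exactly and leaves the first harmonic (used by the
#' reflection coefficient) untouched.
#'
#' @param x numeric vector, one cycle.
#' @param nHarm number of harmonics kept (>= 1); `Inf` returns x.
#' @return Smoothed cycle, same length.
#' @export
harmonicSmooth <- function(x, nHarm = 25) {
  n <- length(x)
  if (!is.finite(nHarm) || nHarm >= floor(n / 2)) return(x)
  X <- fft(x)
  keep <- c(seq_len(nHarm + 1), seq(n - nHarm + 1, n))
  X[setdiff(seq_len(n), keep)] <- 0
  Re(fft(X, inverse = TRUE)) / n
}

#' All vessel metrics from an ensemble-averaged cycle
#'
#' Runs the full metric battery on a [CycleEnsemble-class] containing
#' `area` (mm^2) and `velocity` (mm/s) signals (and optionally
#' `thickness`, mm): flow as the instantaneous area-velocity product,
#' QA-loop PWV, wave separation about the foot baselines, first-harmonic
#' reflection coefficient, pulsatility index, end-diastolic diameter and
#' Moens-Korteweg Young's modulus.
#'
#' @param ens a [CycleEnsemble-class] with signals `area` and `velocity`.
#' @param wallThickness wall thickness, mm; defaults to the median of the
#'   ensemble's `thickness` signal when present (required otherwise).
#' @param rho blood density, kg/m^3.
#' @param side "LCCA" or "RCCA" label carried through to the record.
#' @param nHarm harmonics kept by [harmonicSmooth()] on the mean area and
#'   velocity cycles before metric computation (`Inf` disables).
#' @return A [VesselMetrics-class]; QA diagnostics, cycle counts and the
#'   reciprocal harmonic ratio are stored in `@diagnostics`.
#' @export
computeVesselMetrics <- function(ens, wallThickness = NULL, rho = 1050,
                                 side = NA_character_, nHarm = 25) {
  stopifnot(is(ens, "CycleEnsemble"))
  if (!all(c("area", "velocity") %in% names(ens@meanCycle)))
    stop("ensemble must contain 'area' and 'velocity' signals")
  A <- harmonicSmooth(meanCycle(ens, "area"), nHarm)
  V <- harmonicSmooth(meanCycle(ens, "velocity"), nHarm)
  if (is.null(wallThickness)) {
    if (!"thickness" %in% names(ens@meanCycle))
      stop("wallThickness must be given when the ensemble has no thickness signal")
    wallThickness <- median(meanCycle(ens, "thickness"))
  }

  fl <- flowWaveform(A, V)
  qa <- pwvQALoop(fl$Q_ml_min, A)
  dec <- decomposeWaves(fl$Q_ml_min, A, qa$pwv)
  rc <- reflectionCoefficient(dec$Qf_ml_min, dec$Qr_ml_min)
  dDia <- diameterFromArea(A[1])

  new("VesselMetrics",
      diameter = dDia,
      wallThickness = wallThickness,
      meanFlow = fl$meanFlow,
      heartRate = ens@heartRate,
      pulsatilityIndex = pulsatilityIndex(V),
      pwv = qa$pwv,
      reflectionCoefficient = rc$rc,
      youngsModulus = youngsModulus(qa$pwv, dDia, wallThickness, rho),
      side = side,
      diagnostics = list(qaR2 = qa$r2, qaWindow = qa$window, qaN = qa$n,
                         negativeSlope = qa$negativeSlope,
                         rcReciprocal = rc$reciprocal,
                         nCyclesUsed = ens@nUsed,
                         nCyclesRejected = ens@nRejected,
                         meanCycle = list(t = ens@t, area = A, velocity = V,
                                          Q = fl$Q_ml_min,
                                          Qf = dec$Qf_ml_min,
                                          Qr = dec$Qr_ml_min)))
}
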