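#' Ground-truth hemodynamic parameter set
#'
#' An S4 container for the parameters that define one synthetic carotid
#' recording: wave speed, reflection, geometry, heart rate, the forward
#' flow-pulse shape, blood density and noise levels. All fields are in the
#' conventional units used at the instrument (mm, mL/min, beats/min, s);
#' conversion to SI happens inside the generator.
#'
#' @slot cTrue pulse wave velocity of the simulated vessel, m/s.
#' @slot gammaTrue reflection coefficient magnitude, dimensionless in
#'   `[0, 1)`.
#' @slot tau reflection arrival delay relative to the forward wave, s.
#' @slot dDia end-diastolic inner diameter, mm. The end-diastolic lumen
#'   area is always `pi * dDia^2 / 4` (see [aDia()]).
#' @slot hTrue wall thickness, mm.
#' @slot heartRate heart rate, beats/min.
#' @slot qDia diastolic (baseline) forward flow, mL/min.
#' @slot qAmp amplitude of the systolic forward flow pulse, mL/min.
#' @slot tRise raised-cosine systolic rise time, s. Must end within the
#'   first 40% of the cardiac cycle.
#' @slot tDecay exponential decay time constant of the pulse, s.
#' @slot rho blood density, g/mL (default 1.05).
#' @slot noiseSd additive Gaussian noise level on the waveforms, expressed
#'   as a fraction of each signal's peak-to-peak amplitude.
#' @slot rrJitter fractional RR-interval jitter (heavy-tailed, Student-t
#'   with 3 df), dimensionless.
#' @slot arrProb per-cycle probability of an arrhythmic (prolonged) beat.
#' @slot arrScale RR multiplier applied to arrhythmic beats.
#' @slot seed RNG seed (NA for no seeding).
#' @seealso [hemoTruth()], [synthesizeWaveforms()]
#' @export
setClass("HemoTruth",
  slots = c(
    cTrue = "numeric", gammaTrue = "numeric", tau = "numeric",
    dDia = "numeric", hTrue = "numeric", heartRate = "numeric",
    qDia = "numeric", qAmp = "numeric", tRise = "numeric",
    tDecay = "numeric", rho = "numeric", noiseSd = "numeric",
    rrJitter = "numeric", arrProb = "numeric", arrScale = "numeric",
    seed = "numeric"
  )
)

setValidity("HemoTruth", function(object) {
  msg <- character()
  sc <- function(x) length(x) == 1L && is.finite(x)
  for (nm in c("cTrue", "gammaTrue", "tau", "dDia", "hTrue", "heartRate",
               "qDia", "qAmp", "tRise", "tDecay", "rho", "noiseSd",
               "rrJitter", "arrProb", "arrScale")) {
    if (!sc(slot(object, nm))) msg <- c(msg, paste0(nm, " must be a finite scalar"))
  }
  if (length(msg)) return(msg)
  if (object@cTrue <= 0) msg <- c(msg, "cTrue must be > 0")
  if (object@gammaTrue < 0 || object@gammaTrue >= 1)
    msg <- c(msg, "gammaTrue must be in [0, 1)")
  if (object@tau <= 0) msg <- c(msg, "tau must be > 0")
  if (object@dDia <= 0) msg <- c(msg, "dDia must be > 0")
  if (object@hTrue <= 0) msg <- c(msg, "hTrue must be > 0")
  if (object@heartRate <= 0) msg <- c(msg, "heartRate must be > 0")
  if (object@qDia < 0 || object@qAmp < 0) msg <- c(msg, "flows must be >= 0")
  if (object@rho <= 0) msg <- c(msg, "rho must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@arrProb < 0 || object@arrProb > 1)
    msg <- c(msg, "arrProb must be in [0, 1]")
  period <- 60 / object@heartRate
  if (object@tRise <= 0 || object@tRise > 0.4 * period)
    msg <- c(msg, "tRise must be positive and end within the first 40% of the cycle")
  if (object@tDecay <= 0 || object@tDecay > period)
    msg <- c(msg, "tDecay must be positive and not exceed the cycle duration")
  if (length(msg)) msg else TRUE
})

#' Construct a ground-truth parameter set
#'
#' Defaults describe a healthy adult mouse common carotid artery under
#' light anesthesia: wave speed 3 m/s, reflection coefficient 0.3 arriving
#' 30 ms after the forward wave, diastolic diameter 0.45 mm, wall thickness
#' 0.05 mm, heart rate 450 beats/min, diastolic flow 0.35 mL/min with a
#' 1.4 mL/min systolic pulse (mean flow about 0.8 mL/min), blood density
#' 1.05 g/mL, and 2% additive waveform noise.
#'
#' @param cTrue,gammaTrue,tau,dDia,hTrue,heartRate,qDia,qAmp,tRise,tDecay,rho,noiseSd,rrJitter,arrProb,arrScale,seed
#'   see [HemoTruth-class].
#' @return A validated [HemoTruth-class] object.
#' @examples
#' truth <- hemoTruth(gammaTrue = 0, noiseSd = 0)
#' aDia(truth)
#' @export
hemoTruth <- function(cTrue = 3, gammaTrue = 0.3, tau = 0.03, dDia = 0.45,
                      hTrue = 0.05, heartRate = 450, qDia = 0.35,
                      qAmp = 1.4, tRise = 0.025, tDecay = 0.03,
                      rho = 1.05, noiseSd = 0.02, rrJitter = 0,
                      arrProb = 0, arrScale = 1.6, seed = NA_real_) {
  new("HemoTruth", cTrue = cTrue, gammaTrue = gammaTrue, tau = tau,
      dDia = dDia, hTrue = hTrue, heartRate = heartRate, qDia = qDia,
      qAmp = qAmp, tRise = tRise, tDecay = tDecay, rho = rho,
      noiseSd = noiseSd, rrJitter = rrJitter, arrProb = arrProb,
      arrScale = arrScale, seed = as.numeric(seed))
}

#' End-diastolic lumen area of a truth object
#'
#' @param truth a [HemoTruth-class] object.
#' @return Lumen area `pi * dDia^2 / 4` in mm^2.
#' @export
aDia <- function(truth) pi * truth@dDia^2 / 4

#' Synthetic waveform set with its forward/reflected decomposition
#'
#' Stores the time grid and the observed (possibly noisy) flow, area and
#' velocity waveforms together with the noise-free signals and the true
#' forward and reflected flow components. All slots are in SI units
#' (s, m^3/s, m^2, m/s). The identity `Qf + Qr == Qclean` holds to machine
#' precision; the observed `Q` equals `Qclean` plus additive noise.
#'
#' @slot t time grid, s (uniform step, strictly increasing).
#' @slot Q,A,V observed flow (m^3/s), lumen area (m^2) and mean velocity
#'   (m/s).
#' @slot Qf,Qr true forward and reflected flow components, m^3/s
#'   (noise-free).
#' @slot Qclean,Aclean,Vclean noise-free versions of Q, A, V.
#' @slot cycleStarts true cycle-start times used by the generator, s.
#' @slot truth the generating [HemoTruth-class].
#' @seealso [synthesizeWaveforms()], [waveformTable()]
#' @export
setClass("WaveformPair",
  slots = c(t = "numeric", Q = "numeric", A = "numeric", V = "numeric",
            Qf = "numeric", Qr = "numeric", Qclean = "numeric",
            Aclean = "numeric", Vclean = "numeric",
            cycleStarts = "numeric", truth = "HemoTruth")
)

setValidity("WaveformPair", function(object) {
  n <- length(object@t)
  lens <- vapply(c("Q", "A", "V", "Qf", "Qr", "Qclean", "Aclean", "Vclean"),
                 function(nm) length(slot(object, nm)), integer(1))
  if (any(lens != n)) return("all waveform arrays must have the length of t")
  if (n > 1 && any(diff(object@t) <= 0)) return("t must be strictly increasing")
  if (any(object@A < 0)) return("area must be non-negative")
  scale <- max(abs(object@Qclean), 1e-300)
  if (max(abs(object@Qf + object@Qr - object@Qclean)) > 1e-9 * scale)
    return("Qf + Qr must equal the noise-free flow to machine precision")
  TRUE
})

#' Calibrated M-mode image
#'
#' Depth-by-time intensity image of the vessel: two bright wall bands on a
#' dark lumen, with depth and line-rate calibration.
#'
#' @slot intensity numeric matrix, rows = depth pixels, cols = scan lines.
#' @slot pixelPitch depth sampling, mm/pixel.
#' @slot lineRate scan line rate, Hz.
#' @slot depthOffset depth of the first row's pixel center, mm.
#' @slot meta list of metadata (rendering warnings, provenance).
#' @export
setClass("MModeImage",
  slots = c(intensity = "matrix", pixelPitch = "numeric",
            lineRate = "numeric", depthOffset = "numeric", meta = "list")
)

setValidity("MModeImage", function(object) {
  if (!is.numeric(object@intensity)) return("intensity must be numeric")
  if (any(!is.finite(object@intensity))) return("intensity must be finite")
  if (object@pixelPitch <= 0) return("pixelPitch must be > 0")
  if (object@lineRate <= 0) return("lineRate must be > 0")
  TRUE
})

#' Calibrated pulsed Doppler spectrogram
#'
#' Velocity-by-time intensity image; velocity bin j covers
#' `((j-1) * vBin, j * vBin]` mm/s starting at zero.
#'
#' @slot intensity numeric matrix, rows = velocity bins (low to high),
#'   cols = scan lines.
#' @slot vBin velocity bin width, mm/s.
#' @slot lineRate scan line rate, Hz.
#' @slot meta list of metadata.
#' @export
setClass("DopplerSpectrogram",
  slots = c(intensity = "matrix", vBin = "numeric", lineRate = "numeric",
            meta = "list")
)

setValidity("DopplerSpectrogram", function(object) {
  if (!is.numeric(object@intensity)) return("intensity must be numeric")
  if (any(!is.finite(object@intensity))) return("intensity must be finite")
  if (object@vBin <= 0) return("vBin must be > 0")
  if (object@lineRate <= 0) return("lineRate must be > 0")
  TRUE
})

#' Ensemble of aligned cardiac cycles
#'
#' Cycles segmented at the start of systole, resampled to a fixed number of
#' samples and averaged. All signals share the same feet so area, velocity
#' and derived signals stay sample-aligned.
#'
#' @slot t phase grid of the resampled cycle, s from the foot, length N.
#' @slot cycles named list of matrices (one per signal), each
#'   `nUsed x N`: the retained resampled cycles.
#' @slot meanCycle named list of numeric vectors (length N): the pointwise
#'   mean cycle per signal.
#' @slot nUsed,nRejected number of cycles retained / rejected as
#'   arrhythmic.
#' @slot period median RR interval of retained cycles, s.
#' @slot heartRate 60 / period, beats/min.
#' @slot feet all detected cycle-start times, s.
#' @slot retained indices (into RR intervals) of the retained cycles.
#' @export
setClass("CycleEnsemble",
  slots = c(t = "numeric", cycles = "list", meanCycle = "list",
            nUsed = "integer", nRejected = "integer", period = "numeric",
            heartRate = "numeric", feet = "numeric", retained = "integer")
)

setValidity("CycleEnsemble", function(object) {
  if (object@nUsed < 3L) return("at least 3 cycles must be retained")
  if (abs(object@heartRate - 60 / object@period) > 1e-8 * object@heartRate)
    return("heartRate must equal 60 / period")
  N <- length(object@t)
  dims <- vapply(object@cycles, function(m) identical(dim(m), c(object@nUsed, N)),
                 logical(1))
  if (!all(dims)) return("every cycle matrix must be nUsed x length(t)")
  if (!identical(sort(names(object@cycles)), sort(names(object@meanCycle))))
    return("cycles and meanCycle must hold the same signals")
  if (any(vapply(object@meanCycle, length, integer(1)) != N))
    return("mean cycles must have length(t) samples")
  TRUE
})

#' Per-recording vessel metrics
#'
#' One record per (mouse, age, side): the derived hemodynamic metrics in
#' conventional units, plus QA-loop fit diagnostics.
#'
#' @slot diameter end-diastolic inner diameter, mm.
#' @slot wallThickness wall thickness, mm.
#' @slot meanFlow cycle-averaged blood flow, mL/min.
#' @slot heartRate beats/min.
#' @slot pulsatilityIndex dimensionless.
#' @slot pwv QA-loop pulse wave velocity, m/s.
#' @slot reflectionCoefficient first-harmonic |reflected/forward| ratio.
#' @slot youngsModulus Moens-Korteweg Young's modulus, kPa.
#' @slot side "LCCA", "RCCA" or NA.
#' @slot diagnostics list: QA fit R^2 and window, cycle counts, the
#'   reciprocal harmonic ratio, flags.
#' @export
setClass("VesselMetrics",
  slots = c(diameter = "numeric", wallThickness = "numeric",
            meanFlow = "numeric", heartRate = "numeric",
            pulsatilityIndex = "numeric", pwv = "numeric",
            reflectionCoefficient = "numeric", youngsModulus = "numeric",
            side = "character", diagnostics = "list")
)

setValidity("VesselMetrics", function(object) {
  if (!is.finite(object@pwv)) return("pwv must be finite")
  if (object@pulsatilityIndex < 0) return("pulsatility index must be >= 0")
  if (object@reflectionCoefficient < 0) return("reflection coefficient must be >= 0")
  if (length(object@diagnostics) == 0) return("diagnostics must be populated")
  TRUE
})

#' Longitudinal cohort simulation design
#'
#' @slot nPerGroup mice per genotype-by-sex cell (>= 2).
#' @slot ages imaging ages, days, strictly increasing.
#' @slot effects data.frame with columns `parameter`, `sex`, `age`, `mult`:
#'   multiplicative genotype (dcr vs control) effect per parameter, sex and
#'   age; parameters absent from the table get multiplier 1.
#' @slot ageTrend data.frame with columns `parameter`, `age`, `mult`:
#'   control-trajectory multiplier shared by both genotypes.
#' @slot baseline named numeric: control female LCCA value of each metric
#'   at the first age, in reporting units.
#' @slot sexEffect named numeric: male/female baseline ratio per metric.
#' @slot sideEffect named numeric: RCCA/LCCA ratio per metric.
#' @slot sdBetween named numeric: between-mouse SD (log scale) per metric.
#' @slot sdResidual named numeric: residual SD (log scale) per metric.
#' @slot dropout logical: simulate pre-endpoint death of dcr males.
#' @slot seed RNG seed.
#' @seealso [cohortSpec()], [simulateCohort()]
#' @export
setClass("CohortSpec",
  slots = c(nPerGroup = "integer", ages = "numeric",
            effects = "data.frame", ageTrend = "data.frame",
            baseline = "numeric", sexEffect = "numeric",
            sideEffect = "numeric", sdBetween = "numeric",
            sdResidual = "numeric", dropout = "logical", seed = "numeric")
)

setValidity("CohortSpec", function(object) {
  if (object@nPerGroup < 2L) return("nPerGroup must be >= 2")
  if (length(object@ages) < 1 || any(diff(object@ages) <= 0))
    return("ages must be strictly increasing")
  if (any(object@sdBetween < 0) || any(object@sdResidual < 0))
    return("all SDs must be >= 0")
  need <- cohortMetricNames()
  for (nm in c("baseline", "sexEffect", "sideEffect", "sdBetween", "sdResidual")) {
    if (!all(need %in% names(slot(object, nm))))
      return(paste0(nm, " must name every metric: ", paste(need, collapse = ", ")))
  }
  TRUE
})

#' Linear mixed-effects fit summary
#'
#' @slot outcome outcome column name.
#' @slot coefficients data.frame: term, estimate, se, z, p (Wald normal
#'   approximation).
#' @slot ranefVar random-intercept (mouse) variance.
#' @slot sigma2 residual variance.
#' @slot formula model formula as a string.
#' @slot nObs,nMice numbers of observations and mice.
#' @slot logLik restricted log-likelihood.
#' @slot converged,singular convergence flags.
#' @slot fit the underlying `lmerMod` object.
#' @slot modelData data used for the fit (for releveled refits).
#' @slot callInfo list of the arguments needed to refit (fixed effects,
#'   interactions, age coding, relevels).
#' @export
setClass("LmmResult",
  slots = c(outcome = "character", coefficients = "data.frame",
            ranefVar = "numeric", sigma2 = "numeric", formula = "character",
            nObs = "integer", nMice = "integer", logLik = "numeric",
            converged = "logical", singular = "logical", fit = "ANY",
            modelData = "ANY", callInfo = "list")
)

setValidity("LmmResult", function(object) {
  p <- object@coefficients$p
  if (any(p < 0 | p > 1, na.rm = TRUE)) return("p-values must be in [0, 1]")
  if (object@nObs < object@nMice) return("nObs must be >= nMice")
  if (object@ranefVar < 0 || object@sigma2 < 0) return("variances must be >= 0")
  TRUE
})

#' Empirical ROC curve with Youden cut-off
#'
#' @slot thresholds evaluated cut-offs (midpoints between sorted unique
#'   values, plus -Inf and Inf).
#' @slot sensitivity,specificity per-threshold operating points.
#' @slot auc area under the curve (trapezoid; equals the Mann-Whitney
#'   statistic).
#' @slot youdenCutoff threshold maximising J = sensitivity + specificity
#'   - 1 (ties broken toward the lower cut-off).
#' @slot youdenJ the maximal J.
#' @slot direction pROC-style orientation ("<" when larger predictor
#'   values indicate the positive class); chosen so AUC >= 0.5.
#' @slot positiveClass label treated as positive (diseased).
#' @export
setClass("RocResult",
  slots = c(thresholds = "numeric", sensitivity = "numeric",
            specificity = "numeric", auc = "numeric",
            youdenCutoff = "numeric", youdenJ = "numeric",
            direction = "character", positiveClass = "character")
)

setValidity("RocResult", function(object) {
  if (object@auc < 0 || object@auc > 1) return("AUC must be in [0, 1]")
  if (any(object@sensitivity < 0 | object@sensitivity > 1))
    return("sensitivity must be in [0, 1]")
  if (any(object@specificity < 0 | object@specificity > 1))
    return("specificity must be in [0, 1]")
  if (!isTRUE(any(object@thresholds == object@youdenCutoff)))
    return("the Youden cut-off must be one of the evaluated thresholds")
  TRUE
})
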