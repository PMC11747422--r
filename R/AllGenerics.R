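#' Image intensity matrix
#' @param object an [MModeImage-class] or [DopplerSpectrogram-class].
#' @return The numeric intensity matrix.
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' @rdname intensity
#' @export
setMethod("intensity", "MModeImage", function(object) object@intensity)

#' @rdname intensity
#' @export
setMethod("intensity", "DopplerSpectrogram", function(object) object@intensity)

#' Heart rate accessor
#' @param object a [CycleEnsemble-class] or [VesselMetrics-class].
#' @return Heart rate in beats/min.
#' @export
setGeneric("heartRate", function(object) standardGeneric("heartRate"))

#' @rdname heartRate
#' @export
setMethod("heartRate", "CycleEnsemble", function(object) object@heartRate)

#' @rdname heartRate
#' @export
setMethod("heartRate", "VesselMetrics", function(object) object@heartRate)

#' Mean (ensemble-averaged) cycle
#' @param object a [CycleEnsemble-class].
#' @param signal optional signal name; when missing, all signals.
#' @return A numeric vector (one signal) or named list of vectors.
#' @export
setGeneric("meanCycle", function(object, signal) standardGeneric("meanCycle"))

#' @rdname meanCycle
#' @export
setMethod("meanCycle", "CycleEnsemble", function(object, signal) {
  if (missing(signal)) return(object@meanCycle)
  if (!signal %in% names(object@meanCycle))
    stop("no such signal in the ensemble: ", signal)
  object@meanCycle[[signal]]
})

#' Waveforms as a data.frame
#'
#' @param wf a [WaveformPair-class].
#' @param units `"SI"` (s, m^3/s, m^2, m/s) or `"field"` (s, mL/min, mm^2,
#'   mm/s).
#' @return data.frame with columns t, Q, A, V, Q_f, Q_r.
#' @export
waveformTable <- function(wf, units = c("SI", "field")) {
  units <- match.arg(units)
  d <- data.frame(t = wf@t, Q = wf@Q, A = wf@A, V = wf@V,
                  Q_f = wf@Qf, Q_r = wf@Qr)
  if (units == "field") {
    d$Q <- m3sToMlMin(d$Q); d$Q_f <- m3sToMlMin(d$Q_f)
    d$Q_r <- m3sToMlMin(d$Q_r)
    d$A <- m2ToMm2(d$A); d$V <- mToMm(d$V)
  }
  d
}

#' Vessel metrics as a one-row data.frame
#'
#' Column names carry unit suffixes (the convention used by every metric
#' CSV the package writes).
#'
#' @param metrics a [VesselMetrics-class].
#' @return One-row data.frame.
#' @export
metricsRow <- function(metrics) {
  data.frame(
    side = metrics@side,
    diameter_mm = metrics@diameter,
    wall_thickness_mm = metrics@wallThickness,
    flow_ml_min = metrics@meanFlow,
    heart_rate_bpm = metrics@heartRate,
    pulsatility_index = metrics@pulsatilityIndex,
    pwv_m_s = metrics@pwv,
    reflection_coefficient = metrics@reflectionCoefficient,
    youngs_modulus_kpa = metrics@youngsModulus,
    stringsAsFactors = FALSE
  )
}

setMethod("show", "HemoTruth", function(object) {
  cat("HemoTruth: c =", object@cTrue, "m/s, gamma =", object@gammaTrue,
      ", tau =", object@tau, "s\n")
  cat("  D_dia =", object@dDia, "mm (A_dia =", signif(aDia(object), 5),
      "mm^2), h =", object@hTrue, "mm, HR =", object@heartRate, "bpm\n")
  cat("  pulse: Q_dia =", object@qDia, "mL/min, amplitude =", object@qAmp,
      "mL/min, rise", object@tRise, "s, decay", object@tDecay, "s\n")
  cat("  rho =", object@rho, "g/mL, noise =", object@noiseSd,
      ", RR jitter =", object@rrJitter, ", P(arrhythmia) =",
      object@arrProb, "\n")
})

setMethod("show", "WaveformPair", function(object) {
  cat("WaveformPair:", length(object@t), "samples,",
      length(object@cycleStarts), "cycles,",
      signif(max(object@t), 4), "s (SI units)\n")
  cat("  mean flow", signif(m3sToMlMin(mean(object@Q)), 4),
      "mL/min; diastolic area", signif(m2ToMm2(min(object@Aclean)), 4),
      "mm^2\n")
})

setMethod("show", "MModeImage", function(object) {
  cat("MModeImage:", nrow(object@intensity), "depth px x",
      ncol(object@intensity), "lines;",
      object@pixelPitch, "mm/px,", object@lineRate, "Hz\n")
  if (length(object@meta$warnings))
    cat("  warnings:", paste(object@meta$warnings, collapse = "; "), "\n")
})

setMethod("show", "DopplerSpectrogram", function(object) {
  cat("DopplerSpectrogram:", nrow(object@intensity), "velocity bins x",
      ncol(object@intensity), "lines;", object@vBin, "mm/s per bin,",
      object@lineRate, "Hz\n")
})

setMethod("show", "CycleEnsemble", function(object) {
  cat("CycleEnsemble:", object@nUsed, "cycles used,", object@nRejected,
      "rejected;", length(object@t), "samples/cycle\n")
  cat("  period", signif(object@period, 4), "s; heart rate",
      signif(object@heartRate, 4), "bpm; signals:",
      paste(names(object@meanCycle), collapse = ", "), "\n")
})

setMethod("show", "VesselMetrics", function(object) {
  cat("VesselMetrics", if (!is.na(object@side)) paste0("(", object@side, ")"),
      "\n")
  cat("  diameter", signif(object@diameter, 4), "mm; wall",
      signif(object@wallThickness, 4), "mm; flow",
      signif(object@meanFlow, 4), "mL/min; HR",
      signif(object@heartRate, 4), "bpm\n")
  cat("  PI", signif(object@pulsatilityIndex, 4), "; PWV",
      signif(object@pwv, 4), "m/s; RC",
      signif(object@reflectionCoefficient, 4), "; E",
      signif(object@youngsModulus, 4), "kPa\n")
})

setMethod("show", "LmmResult", function(object) {
  cat("LmmResult:", object@outcome, "~", object@formula, "\n")
  cat("  n =", object@nObs, "observations,", object@nMice,
      "mice; mouse variance", signif(object@ranefVar, 4),
      "; residual variance", signif(object@sigma2, 4), "\n")
  if (!object@converged) cat("  WARNING: fit did not converge\n")
  if (object@singular) cat("  note: singular fit\n")
  print(within(object@coefficients, {
    estimate <- signif(estimate, 4); se <- signif(se, 4)
    z <- signif(z, 3); p <- signif(p, 3)
  }), row.names = FALSE)
})

setMethod("show", "RocResult", function(object) {
  cat("RocResult: AUC =", signif(object@auc, 4), "(positive class",
      object@positiveClass, ", direction", object@direction, ")\n")
  cat("  Youden cut-off", signif(object@youdenCutoff, 4), "with J =",
      signif(object@youdenJ, 4), "\n")
})
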