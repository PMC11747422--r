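# Synthetic-data generator: ground-truth waveforms, rendered M-mode and
# Doppler images, and longitudinal cohorts with planted effects.

# Dimensionless pulse shape on phase phi within one cycle: raised-cosine
# upstroke peaking at tRise, then exponential decay. Zero outside [0, Inf).
pulseShape <- function(phi, tRise, tDecay) {
  s <- numeric(length(phi))
  up <- phi >= 0 & phi <= tRise
  dn <- phi > tRise
  s[up] <- 0.5 * (1 - cos(pi * phi[up] / tRise))
  s[dn] <- exp(-(phi[dn] - tRise) / tDecay)
  s
}

#' Forward flow pulse over one cardiac cycle
#'
#' The forward pulse is a baseline diastolic flow plus a single systolic
#' peak: a raised-cosine upstroke of duration `tRise` (so the peak sits
#' within the first 40% of the cycle) followed by an exponential decay
#' with time constant `tDecay`. Rise or decay times exceeding the cycle
#' duration are rejected at [hemoTruth()] construction.
#'
#' @param truth a [HemoTruth-class].
#' @param fs sampling rate, Hz.
#' @return data.frame with columns `t` (s) and `Q` (mL/min), one cycle.
#' @examples
#' p <- makeForwardPulse(hemoTruth(qAmp = 0))
#' stopifnot(all(p$Q == p$Q[1]))  # zero amplitude: constant baseline
#' @export
makeForwardPulse <- function(truth, fs = 5000) {
  validObject(truth)
  period <- 60 / truth@heartRate
  t <- seq(0, period, by = 1 / fs)
  t <- t[t < period]
  data.frame(t = t,
             Q = truth@qDia + truth@qAmp * pulseShape(t, truth@tRise, truth@tDecay))
}

#' Analytic cycle-mean of the forward flow pulse
#'
#' Closed-form time average of [makeForwardPulse()] over one cycle
#' (raised cosine integrates to half its duration; the truncated
#' exponential to `tDecay * (1 - exp(-(T - tRise)/tDecay))`).
#'
#' @inheritParams makeForwardPulse
#' @return Mean forward flow, mL/min.
#' @export
meanForwardFlow <- function(truth) {
  period <- 60 / truth@heartRate
  area <- truth@tRise / 2 +
    truth@tDecay * (1 - exp(-(period - truth@tRise) / truth@tDecay))
  truth@qDia + truth@qAmp * area / period
}

# Cycle-start times for n cycles, with optional heavy-tailed RR jitter and
# arrhythmic (prolonged) beats. Uses the current RNG state.
cyclePeriods <- function(truth, nCycles) {
  period <- 60 / truth@heartRate
  fac <- rep(1, nCycles)
  if (truth@rrJitter > 0) {
    eps <- truth@rrJitter * rt(nCycles, df = 3) / sqrt(3)
    fac <- fac * (1 + pmax(pmin(eps, 0.35), -0.35))
  }
  if (truth@arrProb > 0) {
    arr <- runif(nCycles) < truth@arrProb
    fac[arr] <- fac[arr] * truth@arrScale
  }
  period * fac
}

#' Synthesize flow, area and velocity waveforms with a planted reflection
#'
#' Implements the linear-wave construction that makes the QA-loop slope
#' equal the wave speed. With forward flow perturbation
#' `q_f(t)` (about the diastolic baseline), the reflected flow is
#' `Q_r(t) = -gamma * q_f(t - tau)` (a reflection opposes net flow), while
#' its area perturbation adds, so
#' `A(t) = A_dia + (q_f(t) + gamma * q_f(t - tau)) / c` in SI units.
#' Net flow is `Q = Q_f + Q_r` and velocity `V = Q / A`. Additive Gaussian
#' noise (fraction `noiseSd` of each signal's peak-to-peak range) is
#' applied after construction; the noise-free signals and the true
#' decomposition are kept alongside.
#'
#' Times before the recording start are wrapped periodically (the vessel is
#' in steady state), so the delayed reflection is defined from t = 0.
#'
#' @param truth a [HemoTruth-class]; `truth@seed` (when not NA) makes the
#'   output reproducible.
#' @param nCycles number of cardiac cycles (>= 3).
#' @param fs sampling rate, Hz.
#' @return A [WaveformPair-class] in SI units.
#' @examples
#' wf <- synthesizeWaveforms(hemoTruth(gammaTrue = 0, noiseSd = 0, seed = 1))
#' # reflection-free: area and flow exactly proportional, slope cTrue
#' range(diff(wf@Q) / diff(wf@A))
#' @export
synthesizeWaveforms <- function(truth, nCycles = 8, fs = 5000) {
  validObject(truth)
  if (nCycles < 3) stop("nCycles must be >= 3")
  if (!is.na(truth@seed)) set.seed(truth@seed)

  periods <- cyclePeriods(truth, nCycles)
  starts <- c(0, cumsum(periods))
  total <- starts[nCycles + 1]
  t <- seq(0, total, by = 1 / fs)
  t <- t[t < total]

  qAmpSI <- mlMinToM3s(truth@qAmp)
  qDiaSI <- mlMinToM3s(truth@qDia)
  aDiaSI <- mm2ToM2(aDia(truth))

  perturb <- function(tt) {
    neg <- tt < 0
    phi <- numeric(length(tt))
    if (any(neg)) phi[neg] <- tt[neg] %% periods[1]
    if (any(!neg)) {
      k <- findInterval(tt[!neg], starts, rightmost.closed = FALSE)
      k <- pmin(k, nCycles)
      phi[!neg] <- tt[!neg] - starts[k]
    }
    qAmpSI * pulseShape(phi, truth@tRise, truth@tDecay)
  }

  qf <- perturb(t)
  qdel <- perturb(t - truth@tau)
  Qf <- qDiaSI + qf
  Qr <- -truth@gammaTrue * qdel
  Q0 <- Qf + Qr
  A0 <- aDiaSI + (qf + truth@gammaTrue * qdel) / truth@cTrue
  V0 <- Q0 / A0

  addNoise <- function(x) {
    if (truth@noiseSd <= 0) return(x)
    x + rnorm(length(x)) * truth@noiseSd * diff(range(x))
  }
  Q <- addNoise(Q0)
  A <- pmax(addNoise(A0), 0.05 * aDiaSI)
  V <- addNoise(V0)

  new("WaveformPair", t = t, Q = Q, A = A, V = V, Qf = Qf, Qr = Qr,
      Qclean = Q0, Aclean = A0, Vclean = V0,
      cycleStarts = starts[seq_len(nCycles)], truth = truth)
}

# Rayleigh multiplier with unit mean (sigma = sqrt(2/pi)).
rayleighUnitMean <- function(n) sqrt(2 / pi) * sqrt(-2 * log(runif(n)))

#' Render an M-mode image from waveforms
#'
#' Draws bright near- and far-wall bands whose separation follows the
#' diameter waveform `D(t) = sqrt(4 A(t) / pi)`. Band centers sit at
#' `centerDepth -/+ D(t)/2` and each band has a Gaussian depth profile with
#' full width at half maximum equal to the wall thickness. Optional
#' multiplicative Rayleigh speckle.
#'
#' @param wf a [WaveformPair-class].
#' @param pixelPitch depth sampling, mm/pixel.
#' @param lineRate scan line rate, Hz.
#' @param centerDepth depth of the vessel center line, mm.
#' @param speckle speckle level in `[0, 1]`: 0 = noiseless, 1 = fully
#'   developed speckle.
#' @param background background intensity of the lumen/tissue.
#' @param seed optional RNG seed for the speckle.
#' @return An [MModeImage-class]. If `pixelPitch` is too coarse to resolve
#'   the wall thickness (pitch > h/2) a warning is recorded in the image
#'   metadata.
#' @export
renderMMode <- function(wf, pixelPitch = 0.01, lineRate = 1000,
                        centerDepth = 0.6, speckle = 0.5,
                        background = 0.05, seed = NA) {
  truth <- wf@truth
  tl <- seq(min(wf@t), max(wf@t), by = 1 / lineRate)
  Amm2 <- m2ToMm2(approx(wf@t, wf@A, xout = tl, rule = 2)$y)
  Dmm <- sqrt(4 * Amm2 / pi)
  h <- truth@hTrue
  zNear <- centerDepth - Dmm / 2
  zFar <- centerDepth + Dmm / 2

  pad <- 6 * h
  z0 <- floor((min(zNear) - pad) / pixelPitch) * pixelPitch
  z <- seq(z0, max(zFar) + pad, by = pixelPitch)
  sigma <- h / (2 * sqrt(2 * log(2)))  # FWHM = h

  I <- background +
    exp(-outer(z, zNear, "-")^2 / (2 * sigma^2)) +
    exp(-outer(z, zFar, "-")^2 / (2 * sigma^2))

  warnings <- character()
  if (pixelPitch > h / 2)
    warnings <- c(warnings,
      sprintf("pixel pitch %.3g mm too coarse to resolve wall thickness %.3g mm",
              pixelPitch, h))

  if (speckle > 0) {
    if (!is.na(seed)) set.seed(seed)
    R <- matrix(rayleighUnitMean(length(I)), nrow = nrow(I))
    I <- I * (1 - speckle + speckle * R)
  }

  new("MModeImage", intensity = I, pixelPitch = pixelPitch,
      lineRate = lineRate, depthOffset = z[1],
      meta = list(warnings = warnings, centerDepth = centerDepth,
                  wallThickness = h))
}

#' Render a pulsed Doppler spectrogram from waveforms
#'
#' Per scan line, intensity fills the velocity bins from zero up to the
#' instantaneous maximum velocity `V_max(t) = 2 V(t)` — the parabolic
#' flow-profile convention whose inverse is the envelope-halving rule used
#' at analysis time. The bin straddling the envelope is partially filled in
#' proportion to coverage. Optional speckle inside the spectrum and an
#' additive noise floor everywhere.
#'
#' @param wf a [WaveformPair-class].
#' @param vBin velocity bin width, mm/s.
#' @param lineRate scan line rate, Hz.
#' @param speckle speckle level in `[0, 1]` applied inside the spectrum.
#' @param noiseFloor scale of the additive half-normal noise floor.
#' @param seed optional RNG seed for the noise.
#' @return A [DopplerSpectrogram-class].
#' @export
renderDoppler <- function(wf, vBin = 5, lineRate = 1000, speckle = 0.5,
                          noiseFloor = 0.05, seed = NA) {
  tl <- seq(min(wf@t), max(wf@t), by = 1 / lineRate)
  Vmms <- mToMm(approx(wf@t, wf@V, xout = tl, rule = 2)$y)
  vMax <- 2 * pmax(Vmms, 0)

  nBins <- max(20L, ceiling((max(vMax) * 1.25) / vBin) + 6L)
  lowEdge <- (seq_len(nBins) - 1) * vBin
  # fill fraction of each bin: 1 below the envelope, partial at the edge
  F <- outer(lowEdge, vMax, function(lo, vm) pmin(pmax((vm - lo) / vBin, 0), 1))

  if (!is.na(seed)) set.seed(seed)
  if (speckle > 0) {
    R <- matrix(rayleighUnitMean(length(F)), nrow = nrow(F))
    F <- F * (1 - speckle + speckle * R)
  }
  if (noiseFloor > 0)
    F <- F + noiseFloor * abs(matrix(rnorm(length(F)), nrow = nrow(F)))

  new("DopplerSpectrogram", intensity = F, vBin = vBin, lineRate = lineRate,
      meta = list(list()))
}

#' Metric names used by the cohort simulator and statistics
#' @return Character vector of the eight metric column stems.
#' @export
cohortMetricNames <- function() {
  c("diameter_mm", "wall_thickness_mm", "flow_ml_min", "heart_rate_bpm",
    "pulsatility_index", "pwv_m_s", "reflection_coefficient",
    "youngs_modulus_kpa")
}

# Default planted genotype (dcr/control) effect table, mirroring the
# reported longitudinal phenotype: males show a larger diameter and lower
# PWV before disease onset, females a flow and heart-rate deficit at the
# first age that reverses late, plus late elevation of PWV, reflection
# coefficient and Young's modulus in females.
defaultEffectTable <- function(ages = c(50, 75, 125)) {
  a1 <- ages[1]; a2 <- ages[min(2, length(ages))]; a3 <- ages[length(ages)]
  eff <- rbind(
    data.frame(parameter = "flow_ml_min", sex = "F",
               age = c(a1, a2, a3), mult = c(0.75, 1.00, 1.10)),
    data.frame(parameter = "flow_ml_min", sex = "M",
               age = c(a1, a2, a3), mult = c(1.00, 0.92, 0.85)),
    data.frame(parameter = "diameter_mm", sex = "M",
               age = c(a1, a2, a3), mult = c(1.12, 1.08, 1.02)),
    data.frame(parameter = "diameter_mm", sex = "F",
               age = c(a1, a2, a3), mult = c(1.00, 1.07, 1.15)),
    data.frame(parameter = "pwv_m_s", sex = "M",
               age = c(a1, a2, a3), mult = c(0.78, 0.74, 0.70)),
    data.frame(parameter = "pwv_m_s", sex = "F",
               age = c(a1, a2, a3), mult = c(1.00, 1.10, 1.21)),
    data.frame(parameter = "heart_rate_bpm", sex = "F",
               age = c(a1, a2, a3), mult = c(0.71, 0.85, 1.00)),
    data.frame(parameter = "heart_rate_bpm", sex = "M",
               age = c(a1, a2, a3), mult = c(1.00, 0.90, 0.80)),
    data.frame(parameter = "pulsatility_index", sex = "F",
               age = c(a1, a2, a3), mult = c(1.20, 1.20, 1.20)),
    data.frame(parameter = "pulsatility_index", sex = "M",
               age = c(a1, a2, a3), mult = c(1.00, 1.15, 1.15)),
    data.frame(parameter = "wall_thickness_mm", sex = c("F", "M"),
               age = a3, mult = c(1.08, 1.08)),
    data.frame(parameter = "reflection_coefficient", sex = "F",
               age = c(a1, a2, a3), mult = c(1.00, 1.10, 1.25)),
    data.frame(parameter = "youngs_modulus_kpa", sex = "F",
               age = c(a1, a2, a3), mult = c(1.00, 1.14, 1.28))
  )
  eff
}

# Control-trajectory (age) multipliers shared by both genotypes: blood flow
# and diameter grow with age in healthy mice.
defaultAgeTrend <- function(ages = c(50, 75, 125)) {
  rbind(
    data.frame(parameter = "flow_ml_min", age = ages,
               mult = seq(1, 1.25, length.out = length(ages))),
    data.frame(parameter = "diameter_mm", age = ages,
               mult = seq(1, 1.06, length.out = length(ages)))
  )
}

#' Construct a cohort simulation design
#'
#' Defaults reproduce the study conditions of the longitudinal experiment
#' the package models: 6 mice per genotype-by-sex cell imaged at 50, 75 and
#' 125 days on both carotids, with the planted genotype effects of
#' [defaultEffectTable] (sex-specific, age-dependent multiplicative
#' shifts), a right-greater-than-left side asymmetry in diameter and flow,
#' log-normal between-mouse heterogeneity and scan-to-scan residual noise
#' at levels typical of small-animal ultrasound repeatability (3-15%
#' coefficients of variation, larger for flow-derived quantities than for
#' geometry).
#'
#' @param nPerGroup mice per genotype-by-sex cell.
#' @param ages imaging ages in days, strictly increasing.
#' @param effects,ageTrend see [CohortSpec-class]; defaults from
#'   [defaultEffectTable] / `defaultAgeTrend`.
#' @param baseline,sexEffect,sideEffect,sdBetween,sdResidual named numeric
#'   vectors over [cohortMetricNames()]; see [CohortSpec-class].
#' @param dropout simulate pre-endpoint death of dcr males before the last
#'   age.
#' @param seed RNG seed.
#' @return A validated [CohortSpec-class].
#' @export
cohortSpec <- function(nPerGroup = 6, ages = c(50, 75, 125),
                       effects = defaultEffectTable(ages),
                       ageTrend = defaultAgeTrend(ages),
                       baseline = NULL, sexEffect = NULL, sideEffect = NULL,
                       sdBetween = NULL, sdResidual = NULL,
                       dropout = TRUE, seed = 1) {
  nm <- cohortMetricNames()
  dflt <- function(x, vals) {
    if (is.null(x)) return(setNames(vals, nm))
    stopifnot(all(nm %in% names(x)))
    x[nm]
  }
  baseline <- dflt(baseline,
    c(0.42, 0.050, 0.60, 450, 2.0, 3.0, 0.35, 90))
  sexEffect <- dflt(sexEffect, c(1.05, 1.05, 1.10, 1.00, 1.00, 1.00, 1.00, 1.00))
  sideEffect <- dflt(sideEffect, c(1.05, 1.00, 1.10, 1.00, 1.00, 1.00, 1.00, 1.00))
  sdBetween <- dflt(sdBetween, c(0.05, 0.08, 0.12, 0.07, 0.10, 0.09, 0.12, 0.15))
  sdResidual <- dflt(sdResidual, c(0.03, 0.06, 0.10, 0.05, 0.08, 0.08, 0.10, 0.12))
  new("CohortSpec", nPerGroup = as.integer(nPerGroup), ages = as.numeric(ages),
      effects = effects, ageTrend = ageTrend, baseline = baseline,
      sexEffect = sexEffect, sideEffect = sideEffect,
      sdBetween = sdBetween, sdResidual = sdResidual,
      dropout = isTRUE(dropout), seed = as.numeric(seed))
}

lookupMult <- function(tab, parameter, sexVal, ageVal) {
  if (is.null(tab) || nrow(tab) == 0) return(1)
  if ("sex" %in% names(tab)) {
    hit <- tab$parameter == parameter & tab$sex == sexVal & tab$age == ageVal
  } else {
    hit <- tab$parameter == parameter & tab$age == ageVal
  }
  if (!any(hit)) 1 else tab$mult[which(hit)[1]]
}

#' Simulate a longitudinal cohort with known ground truth
#'
#' Each mouse receives a log-normal random intercept per metric
#' (between-mouse SD), group-level multiplicative effects (genotype by sex
#' by age, side asymmetry, sex baseline shift, control age trend), and
#' residual log-normal noise per (age, side) observation. Optionally, a
#' third of the dcr males drop out (die) before the final age, producing
#' missing rows flagged `dropout = TRUE`. Alongside the metric table, a
#' per-recording [HemoTruth-class] log is returned so the same cohort can
#' be pushed through the full waveform/image measurement chain.
#'
#' @param spec a [CohortSpec-class].
#' @return A list with elements
#'   \describe{
#'     \item{table}{long-format data.frame: `mouse_id`, `genotype`, `sex`,
#'       `age_days`, `side`, `dropout`, then one column per metric
#'       ([cohortMetricNames()]); dropout rows carry NA metrics.}
#'     \item{truths}{named list of [HemoTruth-class] objects, one per
#'       non-missing (mouse, age, side) row, keyed `mouse/age/side`.}
#'   }
#' @export
simulateCohort <- function(spec) {
  validObject(spec)
  set.seed(spec@seed %% .Machine$integer.max)
  nm <- cohortMetricNames()

  mice <- expand.grid(idx = seq_len(spec@nPerGroup),
                      sex = c("F", "M"), genotype = c("control", "dcr"),
                      stringsAsFactors = FALSE)
  mice$mouse_id <- sprintf("%s_%s_%02d", mice$genotype, mice$sex, mice$idx)

  intercepts <- matrix(rnorm(nrow(mice) * length(nm)), nrow = nrow(mice))
  intercepts <- sweep(intercepts, 2, spec@sdBetween[nm], `*`)
  colnames(intercepts) <- nm

  # dropout: each dcr male independently at risk; died mice miss the last age
  died <- rep(FALSE, nrow(mice))
  if (spec@dropout && length(spec@ages) > 1) {
    atRisk <- mice$genotype == "dcr" & mice$sex == "M"
    died[atRisk] <- runif(sum(atRisk)) < 1 / 3
  }

  rows <- list()
  truths <- list()
  rowIdx <- 0L
  for (i in seq_len(nrow(mice))) {
    for (age in spec@ages) {
      for (side in c("LCCA", "RCCA")) {
        rowIdx <- rowIdx + 1L
        isDrop <- died[i] && age == spec@ages[length(spec@ages)]
        vals <- setNames(rep(NA_real_, length(nm)), nm)
        if (!isDrop) {
          for (p in nm) {
            mult <- spec@baseline[[p]] *
              (if (mice$sex[i] == "M") spec@sexEffect[[p]] else 1) *
              (if (side == "RCCA") spec@sideEffect[[p]] else 1) *
              lookupMult(spec@ageTrend, p, NULL, age) *
              (if (mice$genotype[i] == "dcr")
                 lookupMult(spec@effects, p, mice$sex[i], age) else 1)
            vals[[p]] <- mult * exp(intercepts[i, p]) *
              exp(rnorm(1, 0, spec@sdResidual[[p]]))
          }
          key <- paste(mice$mouse_id[i], age, side, sep = "/")
          truths[[key]] <- hemoTruthFromMetrics(
            vals, seed = (spec@seed * 977 + rowIdx) %% .Machine$integer.max,
            arrhythmic = mice$genotype[i] == "dcr")
        }
        rows[[rowIdx]] <- data.frame(
          mouse_id = mice$mouse_id[i], genotype = mice$genotype[i],
          sex = mice$sex[i], age_days = age, side = side,
          dropout = isDrop, t(vals), stringsAsFactors = FALSE)
      }
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(table = table, truths = truths)
}

#' Build a waveform-level truth from realized cohort metrics
#'
#' Maps one row of a simulated cohort onto the generator's parameters: the
#' realized PWV becomes the wave speed, the realized diameter, wall
#' thickness and heart rate set the geometry and timing, the realized
#' reflection coefficient becomes the planted reflection magnitude, and
#' the pulse amplitudes are scaled so the analytic cycle-mean net flow
#' (forward minus reflected) matches the realized flow. Pulsatility index
#' and Young's modulus are not plantable at waveform level; they emerge
#' from the shape and from the Moens-Korteweg relation.
#'
#' @param vals named numeric over [cohortMetricNames()].
#' @param seed per-recording seed.
#' @param arrhythmic give the recording occasional arrhythmic beats
#'   (RR jitter 1%, 8% prolonged-beat probability), as seen in diseased
#'   animals.
#' @param noiseSd waveform noise level.
#' @return A [HemoTruth-class].
#' @export
hemoTruthFromMetrics <- function(vals, seed = NA, arrhythmic = FALSE,
                                 noiseSd = 0.02) {
  hr <- vals[["heart_rate_bpm"]]
  period <- 60 / hr
  tRise <- min(0.025, 0.35 * period)
  tDecay <- min(0.03, 0.5 * period)
  gamma <- min(vals[["reflection_coefficient"]], 0.9)
  # scale the default pulse (ratio qAmp/qDia fixed) to hit the target mean
  shapeArea <- tRise / 2 + tDecay * (1 - exp(-(period - tRise) / tDecay))
  qDia0 <- 0.35; qAmp0 <- 1.4
  mean0 <- qDia0 + (1 - gamma) * qAmp0 * shapeArea / period
  scl <- vals[["flow_ml_min"]] / mean0
  hemoTruth(
    cTrue = vals[["pwv_m_s"]], gammaTrue = gamma, tau = 0.03,
    dDia = vals[["diameter_mm"]], hTrue = vals[["wall_thickness_mm"]],
    heartRate = hr, qDia = qDia0 * scl, qAmp = qAmp0 * scl,
    tRise = tRise, tDecay = tDecay, noiseSd = noiseSd,
    rrJitter = if (arrhythmic) 0.01 else 0.005,
    arrProb = if (arrhythmic) 0.08 else 0,
    seed = as.numeric(seed))
}
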