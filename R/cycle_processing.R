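# Cardiac-cycle segmentation at the start of systole, arrhythmia
# rejection, alignment, resampling and ensemble averaging.

#' Detect cycle feet (start of systole) by intersecting tangents
#'
#' Systolic upstrokes are located as well-separated local maxima of the
#' signal's first derivative. For each upstroke, the foot is the
#' intersection of the horizontal tangent through the pre-upstroke minimum
#' with the tangent at the point of maximum upstroke slope — the
#' intersecting-tangents convention for the start of systole.
#'
#' Feet are detected on one reference signal (normally velocity or flow)
#' and reused to segment all phase-locked signals.
#'
#' @param t time vector, s (uniform sampling).
#' @param x reference signal (velocity or flow).
#' @param slopeFrac derivative peaks below `slopeFrac` times the global
#'   maximum slope are not upstrokes.
#' @param minRRFrac candidate upstrokes closer than this fraction of the
#'   median upstroke spacing are merged (largest slope wins).
#' @param smoothMs Gaussian pre-smoothing sigma, ms, applied before
#'   differentiation (noise on the raw trace would otherwise dominate the
#'   slope estimate at high sampling rates); 0 disables.
#' @return Strictly increasing foot times, s. Fails with a diagnostic if
#'   fewer than three feet are found (e.g. on a constant signal).
#' @export
detectSystoleFeet <- function(t, x, slopeFrac = 0.5, minRRFrac = 0.5,
                              smoothMs = 2) {
  n <- length(x)
  stopifnot(length(t) == n, n >= 8)
  dt <- median(diff(t))
  if (smoothMs > 0) {
    sigmaS <- smoothMs / 1000 / dt
    if (sigmaS > 0.3) {
      half <- max(1L, min(ceiling(3 * sigmaS), n - 1))
      k <- exp(-(-half:half)^2 / (2 * sigmaS^2))
      k <- k / sum(k)
      xp <- c(x[half:1], x, x[n:(n - half + 1)])  # reflective padding
      xs <- as.numeric(stats::filter(xp, k, sides = 2))
      x <- xs[(half + 1):(half + n)]
    }
  }
  dx <- c(NA, (x[3:n] - x[1:(n - 2)]) / (2 * dt), NA)

  amp <- max(x) - min(x)
  if (amp <= 1e-12 * max(abs(x), 1) || all(is.na(dx)))
    stop("foot detection failed: no systolic upstrokes (signal is constant)")
  # robust reference slope: a high quantile rather than the maximum, so a
  # single glitch line cannot mask every true upstroke
  smax <- quantile(dx, 0.995, na.rm = TRUE, names = FALSE)
  if (smax <= 0)
    stop("foot detection failed: signal never rises")

  cand <- which(dx > slopeFrac * smax)
  if (!length(cand))
    stop("foot detection failed: no upstroke exceeds the slope threshold")
  # group consecutive candidates into upstroke events, keep each group's
  # steepest sample
  grp <- cumsum(c(1, diff(cand) > 3))
  events <- vapply(split(cand, grp), function(ix) ix[which.max(dx[ix])],
                   numeric(1))
  events <- sort(events)
  # enforce a minimum spacing (greedy, steepest first)
  if (length(events) > 1) {
    minSep <- minRRFrac * median(diff(events))
    keep <- logical(length(events))
    for (i in order(dx[events], decreasing = TRUE)) {
      if (!any(keep & abs(events - events[i]) < minSep)) keep[i] <- TRUE
    }
    events <- sort(events[keep])
  }

  medSpace <- if (length(events) > 1) median(diff(events)) * dt else
    (max(t) - min(t)) / 2
  feet <- numeric(0)
  for (m in events) {
    i0 <- max(1, m - round(0.5 * medSpace / dt))
    vmin <- min(x[i0:m])
    tfoot <- t[m] - (x[m] - vmin) / dx[m]
    if (length(feet) && tfoot <= feet[length(feet)]) next
    feet <- c(feet, tfoot)
  }
  if (length(feet) < 3)
    stop(sprintf("foot detection failed: only %d feet found (need >= 3)",
                 length(feet)))
  feet
}

#' Reject arrhythmic cycles by RR deviation
#'
#' Cycles whose RR interval deviates from the median RR by more than
#' `tol` (a fraction of the median) are excluded; the exclusion is
#' reported so it can be logged.
#'
#' @param feet cycle-start times from [detectSystoleFeet()].
#' @param tol maximum tolerated fractional deviation from the median RR.
#' @return list: `retained` and `rejected` (cycle indices into the RR
#'   sequence), `rr` (all RR intervals, s), `medianRR`.
#' @export
rejectArrhythmic <- function(feet, tol = 0.2) {
  rr <- diff(feet)
  if (!length(rr)) stop("need at least two feet")
  med <- median(rr)
  keep <- abs(rr - med) / med <= tol
  list(retained = which(keep), rejected = which(!keep), rr = rr,
       medianRR = med)
}

#' Segment, align, resample and ensemble-average cardiac cycles
#'
#' Each retained cycle (from one foot to the next) is linearly resampled
#' to `N` samples and the pointwise mean across cycles is taken per
#' signal. All signals share the same feet, so they stay sample-aligned.
#' The last partial cycle (after the final foot) is always discarded. The
#' heart rate is 60 over the median retained RR interval.
#'
#' @param t common time vector of all signals, s.
#' @param signals named list of numeric vectors (same length as `t`),
#'   e.g. `list(area = ..., velocity = ...)`.
#' @param feet cycle-start times from [detectSystoleFeet()].
#' @param N samples per resampled cycle (default 256).
#' @param tol RR rejection tolerance passed to [rejectArrhythmic()];
#'   `NULL` disables rejection.
#' @return A [CycleEnsemble-class].
#' @export
ensembleAverage <- function(t, signals, feet, N = 256L, tol = 0.2) {
  stopifnot(is.list(signals), length(signals) >= 1, !is.null(names(signals)))
  nCyc <- length(feet) - 1
  if (nCyc < 1) stop("need at least one complete cycle")
  if (is.null(tol)) {
    rej <- list(retained = seq_len(nCyc), rejected = integer(0),
                rr = diff(feet), medianRR = median(diff(feet)))
  } else {
    rej <- rejectArrhythmic(feet, tol)
  }
  if (length(rej$retained) < 3)
    stop(sprintf("only %d usable cycles after arrhythmia rejection (need >= 3)",
                 length(rej$retained)))

  period <- median(rej$rr[rej$retained])
  phase <- seq(0, period, length.out = N + 1)[seq_len(N)]

  cycles <- lapply(signals, function(x) {
    m <- matrix(NA_real_, length(rej$retained), N)
    for (r in seq_along(rej$retained)) {
      k <- rej$retained[r]
      grid <- seq(feet[k], feet[k + 1], length.out = N + 1)[seq_len(N)]
      m[r, ] <- approx(t, x, xout = grid, rule = 2)$y
    }
    m
  })
  meanCyc <- lapply(cycles, colMeans)

  new("CycleEnsemble", t = phase, cycles = cycles, meanCycle = meanCyc,
      nUsed = length(rej$retained), nRejected = length(rej$rejected),
      period = period, heartRate = 60 / period, feet = feet,
      retained = as.integer(rej$retained))
}
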