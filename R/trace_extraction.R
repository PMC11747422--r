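# Recovery of wall-position and velocity-envelope time series from the
# calibrated images.

# Gaussian smoothing along the depth axis (columns untouched). The kernel
# is renormalised at the edges.
smoothDepth <- function(I, sigmaPx) {
  if (sigmaPx <= 0) return(I)
  half <- max(1L, ceiling(3 * sigmaPx))
  k <- exp(-(-half:half)^2 / (2 * sigmaPx^2))
  n <- nrow(I)
  K <- matrix(0, n, n)
  for (d in -half:half) {
    idx <- seq_len(n)
    j <- idx + d
    ok <- j >= 1 & j <= n
    K[cbind(idx[ok], j[ok])] <- k[d + half + 1]
  }
  K <- K / rowSums(K)
  K %*% I
}

# Sub-pixel peak center by parabolic interpolation around an index.
parabolicPeak <- function(y, i) {
  if (i <= 1 || i >= length(y)) return(i)
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom >= 0) return(i)
  i + 0.5 * (y[i - 1] - y[i + 1]) / denom
}

# Full width at half maximum around a peak index, by linear interpolation
# of the half-maximum crossings; NA when a crossing is not found.
peakFWHM <- function(y, i, baseline = 0) {
  half <- baseline + (y[i] - baseline) / 2
  l <- i
  while (l > 1 && y[l] > half) l <- l - 1
  r <- i
  while (r < length(y) && y[r] > half) r <- r + 1
  if (y[l] > half || y[r] > half) return(NA_real_)
  xl <- l + (half - y[l]) / (y[l + 1] - y[l])
  xr <- (r - 1) + (y[r - 1] - half) / (y[r - 1] - y[r])
  xr - xl
}

#' Outline the vessel walls in an M-mode image
#'
#' Per scan line, the depth profile is Gaussian-smoothed and the two
#' dominant bright bands are located (the two highest local maxima
#' separated by at least `minGapMm`). Band centers, refined to sub-pixel
#' accuracy by parabolic interpolation of the Gaussian-smoothed profile
#' (the smoothing kernel acts as a matched filter for the band), are
#' reported as the wall depths;
#' band full-widths-at-half-maximum (corrected for the smoothing kernel)
#' as the wall thicknesses. Traces are median-filtered in time. The lumen
#' diameter is the far-minus-near center distance, which matches the
#' band-center convention of the renderer, so render-extract round-trips
#' are exact up to quantization.
#'
#' @param img an [MModeImage-class] with the lumen darker than the walls.
#' @param smoothPx Gaussian smoothing sigma along depth, pixels.
#' @param minGapMm minimum center-to-center wall separation, mm.
#' @param minRel peaks below `minRel` times the column maximum (above
#'   background) are ignored.
#' @param medianWidth odd width of the temporal median filter, samples.
#' @param maxBadFrac maximum tolerated fraction of scan lines with fewer
#'   than two detectable bands before extraction fails.
#' @return data.frame (`t_s`, `near_wall_mm`, `far_wall_mm`,
#'   `near_thickness_mm`, `far_thickness_mm`, `diameter_mm`).
#' @export
outlineWalls <- function(img, smoothPx = 2, minGapMm = 0.15, minRel = 0.3,
                         medianWidth = 3, maxBadFrac = 0.10) {
  I <- intensity(img)
  nz <- nrow(I); nt <- ncol(I)
  Is <- smoothDepth(I, smoothPx)
  gapPx <- minGapMm / img@pixelPitch

  bg <- apply(Is, 2, quantile, probs = 0.2)
  near <- far <- nearW <- farW <- rep(NA_real_, nt)

  for (j in seq_len(nt)) {
    y <- Is[, j]
    core <- 2:(nz - 1)
    isPk <- y[core] > y[core - 1] & y[core] >= y[core + 1] &
      y[core] > bg[j] + minRel * (max(y) - bg[j])
    pk <- core[isPk]
    if (length(pk) < 2) next
    ord <- pk[order(y[pk], decreasing = TRUE)]
    p1 <- ord[1]
    p2cand <- ord[abs(ord - p1) >= gapPx]
    if (!length(p2cand)) next
    p2 <- p2cand[1]
    w1 <- peakFWHM(y, p1, baseline = bg[j])
    w2 <- peakFWHM(y, p2, baseline = bg[j])
    c1 <- parabolicPeak(y, p1); c2 <- parabolicPeak(y, p2)
    if (c1 > c2) { tmp <- c1; c1 <- c2; c2 <- tmp; tmp <- w1; w1 <- w2; w2 <- tmp }
    near[j] <- c1; far[j] <- c2; nearW[j] <- w1; farW[j] <- w2
  }

  bad <- is.na(near)
  if (mean(bad) > maxBadFrac)
    stop(sprintf(
      "wall outline failed: two bands detected in only %.0f%% of %d scan lines",
      100 * mean(!bad), nt))

  fillInterp <- function(x) {
    if (!any(is.na(x))) return(x)
    idx <- seq_along(x)
    approx(idx[!is.na(x)], x[!is.na(x)], xout = idx, rule = 2)$y
  }
  medfilt <- function(x) {
    w <- min(medianWidth, length(x) - (1 - length(x) %% 2))
    if (w >= 3) as.numeric(runmed(x, w, endrule = "median")) else x
  }
  near <- medfilt(fillInterp(near)); far <- medfilt(fillInterp(far))
  nearW <- medfilt(fillInterp(nearW)); farW <- medfilt(fillInterp(farW))

  toMm <- function(px) img@depthOffset + (px - 1) * img@pixelPitch
  # deconvolve the smoothing kernel from the measured FWHM (quadrature)
  fwKernel <- 2 * sqrt(2 * log(2)) * smoothPx
  toWidth <- function(wpx) sqrt(pmax(wpx^2 - fwKernel^2, 1e-6)) * img@pixelPitch

  out <- data.frame(
    t_s = (seq_len(nt) - 1) / img@lineRate,
    near_wall_mm = toMm(near), far_wall_mm = toMm(far),
    near_thickness_mm = toWidth(nearW), far_thickness_mm = toWidth(farW))
  out$diameter_mm <- out$far_wall_mm - out$near_wall_mm
  if (any(out$diameter_mm <= 0))
    stop("wall outline failed: far wall not below near wall everywhere")
  out
}

#' Trace the maximum-velocity envelope of a Doppler spectrogram
#'
#' Per scan line, the envelope lies in the highest velocity bin whose
#' intensity exceeds a threshold estimated from the noise floor (the 95th
#' percentile of the top decile of velocity bins, which lie above any
#' physiological velocity). Within that edge bin the envelope position is
#' refined by intensity interpolation: a partially covered bin is
#' partially filled, so its (clamped) intensity estimates the sub-bin
#' fraction — exact at zero noise. The traced envelope is median-filtered
#' (width 3 by default: rejects single-line dropouts without flattening
#' the systolic peak), and the mean velocity is the envelope divided by
#' two (parabolic-profile halving rule).
#'
#' Raising the threshold can only lower the traced envelope (monotone by
#' construction).
#'
#' @param spec a [DopplerSpectrogram-class].
#' @param thresholdQuantile quantile of the noise-floor sample used as
#'   threshold.
#' @param medianWidth odd width of the temporal median filter.
#' @return data.frame (`t_s`, `v_max_mms`, `v_mean_mms`). An all-zero
#'   spectrogram yields a zero envelope with a warning.
#' @export
traceEnvelope <- function(spec, thresholdQuantile = 0.95, medianWidth = 3) {
  I <- intensity(spec)
  nb <- nrow(I); nt <- ncol(I)
  noiseRows <- max(1L, ceiling(0.9 * nb)):nb
  thr <- max(quantile(I[noiseRows, ], thresholdQuantile), 1e-9)

  # envelope bin: top of the highest run of 3 consecutive supra-threshold
  # bins (isolated noise excursions above the envelope are not runs);
  # columns with fewer than 3 lit bins fall back to the single-bin rule.
  M <- I > thr
  idx <- apply(M, 2, function(col) {
    w <- which(col)
    if (!length(w)) return(0L)
    nbv <- length(col)
    run <- if (nbv >= 3) {
      j <- 3:nbv
      j[col[j] & col[j - 1] & col[j - 2]]
    } else integer(0)
    if (length(run)) max(run) else max(w)
  })
  if (all(idx == 0L)) {
    warning("empty spectrogram: no intensity above the noise floor")
    env <- rep(0, nt)
  } else {
    frac <- vapply(seq_len(nt), function(j)
      if (idx[j] == 0L) 0 else min(max(I[idx[j], j], 0), 1), numeric(1))
    env <- ifelse(idx == 0L, 0, (idx - 1 + frac) * spec@vBin)
    w <- min(medianWidth, nt - (1 - nt %% 2))
    if (w >= 3) env <- as.numeric(runmed(env, w, endrule = "median"))
  }
  data.frame(t_s = (seq_len(nt) - 1) / spec@lineRate,
             v_max_mms = env, v_mean_mms = env / 2)
}
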