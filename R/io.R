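# CSV / TIFF / JSON-sidecar I/O. Every metric CSV carries unit suffixes in
# its header; readers refuse unitless files.

sidecarPath <- function(path) paste0(path, ".json")

writeSidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

readSidecar <- function(path) {
  sp <- sidecarPath(path)
  if (!file.exists(sp)) stop("missing calibration sidecar: ", sp)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write / read waveforms as CSV with a units sidecar
#'
#' Columns `t, Q, A, V, Q_f, Q_r` in SI units; the sidecar JSON records
#' the units and the generating truth parameters.
#'
#' @param wf a [WaveformPair-class].
#' @param path CSV path (a `.json` sidecar is written next to it).
#' @return `writeWaveformCSV`: the path, invisibly. `readWaveformCSV`:
#'   a data.frame with the waveform columns (SI units).
#' @export
writeWaveformCSV <- function(wf, path) {
  write.csv(waveformTable(wf, units = "SI"), path, row.names = FALSE)
  tr <- wf@truth
  writeSidecar(path, list(
    units = list(t = "s", Q = "m3/s", A = "m2", V = "m/s",
                 Q_f = "m3/s", Q_r = "m3/s"),
    truth = list(c_ms = tr@cTrue, gamma = tr@gammaTrue, tau_s = tr@tau,
                 d_dia_mm = tr@dDia, h_mm = tr@hTrue,
                 heart_rate_bpm = tr@heartRate, rho_g_ml = tr@rho,
                 noise_sd = tr@noiseSd, seed = tr@seed)))
  invisible(path)
}

#' @rdname writeWaveformCSV
#' @export
readWaveformCSV <- function(path) {
  meta <- readSidecar(path)
  if (!identical(meta$units$Q, "m3/s"))
    stop("waveform CSV is not in SI units (sidecar says Q in ",
         meta$units$Q, ")")
  d <- read.csv(path)
  need <- c("t", "Q", "A", "V", "Q_f", "Q_r")
  if (!all(need %in% names(d)))
    stop("waveform CSV lacks columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  attr(d, "sidecar") <- meta
  d
}

# TIFF images are stored normalized to [0, 1]; the scale and the
# calibration live in the sidecar.
writeImageTIFF <- function(mat, path, cal) {
  scale <- max(mat, 1e-12)
  tiff::writeTIFF(mat / scale, path, bits.per.sample = 16L)
  writeSidecar(path, c(cal, list(intensity_scale = scale)))
  invisible(path)
}

#' Write / read calibrated images as TIFF plus JSON sidecar
#'
#' Single-channel TIFF (16-bit, intensity normalized; the scale is in the
#' sidecar along with `pixel_pitch_mm` / `v_bin_mm_s` and `line_rate_hz`).
#'
#' @param img an [MModeImage-class] / [DopplerSpectrogram-class].
#' @param path TIFF path.
#' @return write: the path, invisibly; read: the reconstructed object.
#' @export
writeMModeTIFF <- function(img, path) {
  writeImageTIFF(img@intensity, path,
                 list(kind = "mmode", pixel_pitch_mm = img@pixelPitch,
                      line_rate_hz = img@lineRate,
                      depth_offset_mm = img@depthOffset))
}

#' @rdname writeMModeTIFF
#' @export
readMModeTIFF <- function(path) {
  meta <- readSidecar(path)
  if (!identical(meta$kind, "mmode")) stop("not an M-mode sidecar: ", path)
  I <- tiff::readTIFF(path) * meta$intensity_scale
  new("MModeImage", intensity = I, pixelPitch = meta$pixel_pitch_mm,
      lineRate = meta$line_rate_hz, depthOffset = meta$depth_offset_mm,
      meta = list(warnings = character()))
}

#' @rdname writeMModeTIFF
#' @export
writeDopplerTIFF <- function(img, path) {
  writeImageTIFF(img@intensity, path,
                 list(kind = "doppler", v_bin_mm_s = img@vBin,
                      line_rate_hz = img@lineRate))
}

#' @rdname writeMModeTIFF
#' @export
readDopplerTIFF <- function(path) {
  meta <- readSidecar(path)
  if (!identical(meta$kind, "doppler")) stop("not a Doppler sidecar: ", path)
  I <- tiff::readTIFF(path) * meta$intensity_scale
  new("DopplerSpectrogram", intensity = I, vBin = meta$v_bin_mm_s,
      lineRate = meta$line_rate_hz, meta = list())
}

cohortUnitColumns <- function() {
  c("diameter_mm", "wall_thickness_mm", "flow_ml_min", "heart_rate_bpm",
    "pwv_m_s", "youngs_modulus_kpa")
}

#' Write / read a cohort metric table as CSV
#'
#' The header embeds units as column-name suffixes (`_mm`, `_ml_min`,
#' `_bpm`, `_m_s`, `_kpa`); `readCohortCSV` refuses files whose metric
#' columns lack them.
#'
#' @param table cohort metric table.
#' @param path CSV path.
#' @return write: the path, invisibly; read: the data.frame.
#' @export
writeCohortCSV <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortCSV
#' @export
readCohortCSV <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  hasUnits <- any(cohortUnitColumns() %in% names(d))
  if (!hasUnits)
    stop("refusing unitless metric file: expected unit-suffixed columns like ",
         paste(head(cohortUnitColumns(), 3), collapse = ", "))
  d
}

#' Write an ensemble's mean cycle as CSV plus JSON metadata
#'
#' @param ens a [CycleEnsemble-class].
#' @param path CSV path; the JSON sidecar records `n_used`, `n_rejected`
#'   and `heart_rate_bpm`.
#' @return The path, invisibly.
#' @export
writeEnsembleCSV <- function(ens, path) {
  d <- data.frame(t_s = ens@t)
  for (nm in names(ens@meanCycle)) d[[nm]] <- ens@meanCycle[[nm]]
  write.csv(d, path, row.names = FALSE)
  writeSidecar(path, list(n_used = ens@nUsed, n_rejected = ens@nRejected,
                          heart_rate_bpm = ens@heartRate,
                          period_s = ens@period))
  invisible(path)
}
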