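# Helpers shared across test files: run the waveform-level measurement
# chain (no images) and the image-level chain on a truth object.

chainMetricsDirect <- function(truth, nCycles = 8, N = 256) {
  wf <- synthesizeWaveforms(truth, nCycles = nCycles)
  t <- wf@t
  A <- m2ToMm2_test(wf@A)
  V <- mToMm_test(wf@V)
  feet <- detectSystoleFeet(t, V)
  ens <- ensembleAverage(t, list(area = A, velocity = V), feet, N = N)
  computeVesselMetrics(ens, wallThickness = truth@hTrue)
}

# local unit helpers (the package keeps its converters internal)
m2ToMm2_test <- function(x) x * 1e6
mToMm_test <- function(x) x * 1e3
mlMinFromM3s_test <- function(x) x * 6e7

nullEffectTable <- function() {
  data.frame(parameter = character(), sex = character(),
             age = numeric(), mult = numeric())
}
nullAgeTrend <- function() {
  data.frame(parameter = character(), age = numeric(), mult = numeric())
}

zeroSdVec <- function() {
  stats::setNames(rep(0, length(cohortMetricNames())), cohortMetricNames())
}
oneVec <- function() {
  stats::setNames(rep(1, length(cohortMetricNames())), cohortMetricNames())
}
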