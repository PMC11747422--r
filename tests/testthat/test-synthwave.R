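test_that("forward pulse is a baseline plus an early systolic peak", {
  truth <- hemoTruth(qAmp = 0, noiseSd = 0)
  p <- makeForwardPulse(truth)
  expect_true(all(p$Q == truth@qDia))  # zero amplitude: constant baseline

  truth <- hemoTruth(noiseSd = 0)
  p <- makeForwardPulse(truth)
  period <- 60 / truth@heartRate
  expect_equal(max(p$Q), truth@qDia + truth@qAmp, tolerance = 1e-12)
  expect_lt(p$t[which.max(p$Q)], 0.4 * period)
  expect_true(all(p$Q >= 0))
})

test_that("pulse cycle-mean matches trapezoidal quadrature", {
  truth <- hemoTruth(noiseSd = 0)
  p <- makeForwardPulse(truth, fs = 2e5)
  dt <- diff(p$t[1:2])
  trap <- sum((p$Q[-1] + p$Q[-length(p$Q)]) / 2) * dt
  # close the period: last interval wraps to Q[1]
  trap <- trap + (p$Q[length(p$Q)] + p$Q[1]) / 2 * dt
  period <- 60 / truth@heartRate
  expect_equal(trap / period, meanForwardFlow(truth), tolerance = 1e-5)
})

test_that("rise times exceeding 40% of the cycle are rejected", {
  expect_error(hemoTruth(tRise = 0.06, heartRate = 450), "40%")
  expect_error(hemoTruth(tDecay = 0.2, heartRate = 450), "cycle duration")
})

test_that("synthesized waveforms obey the linear-wave construction", {
  truth <- hemoTruth(gammaTrue = 0.3, noiseSd = 0, seed = 1)
  wf <- synthesizeWaveforms(truth)
  # conservation to machine precision before noise
  expect_lt(max(abs(wf@Qf + wf@Qr - wf@Qclean)), 1e-15 * max(abs(wf@Qclean)))
  expect_true(all(diff(wf@t) > 0))
  expect_error(synthesizeWaveforms(truth, nCycles = 2), ">= 3")
})

test_that("reflection-free waveforms have dQ/dA = c everywhere", {
  truth <- hemoTruth(gammaTrue = 0, noiseSd = 0, seed = 1)
  wf <- synthesizeWaveforms(truth)
  dQ <- diff(wf@Q); dA <- diff(wf@A)
  sel <- abs(dA) > 1e-3 * max(abs(dA))
  expect_equal(dQ[sel] / dA[sel], rep(truth@cTrue, sum(sel)),
               tolerance = 1e-9)
})

test_that("early-systolic QA slope equals c when the reflection is late", {
  truth <- hemoTruth(gammaTrue = 0.3, tau = 0.06, heartRate = 300,
                     noiseSd = 0, seed = 1)
  wf <- synthesizeWaveforms(truth)
  # within the first cycle, before the reflection arrives, on the upstroke
  sel <- wf@t > 0.002 & wf@t < truth@tau - 0.005 & wf@t < truth@tRise
  slope <- coef(lm(wf@Q[sel] ~ wf@A[sel]))[2]
  expect_equal(unname(slope), truth@cTrue, tolerance = 0.02)
})

test_that("same seed reproduces identical waveforms", {
  truth <- hemoTruth(noiseSd = 0.05, rrJitter = 0.02, arrProb = 0.2, seed = 7)
  wf1 <- synthesizeWaveforms(truth)
  wf2 <- synthesizeWaveforms(truth)
  expect_identical(wf1@Q, wf2@Q)
  expect_identical(wf1@A, wf2@A)
  expect_identical(wf1@cycleStarts, wf2@cycleStarts)
})

test_that("M-mode rendering places flat wall bands for constant area", {
  truth <- hemoTruth(gammaTrue = 0, qAmp = 0, noiseSd = 0, seed = 1)
  wf <- synthesizeWaveforms(truth)
  img <- renderMMode(wf, speckle = 0)
  I <- intensity(img)
  # every column identical: flat bands
  expect_lt(max(apply(I, 1, function(r) diff(range(r)))), 1e-10)
  # two bright bands separated by the diastolic diameter
  pk <- order(I[, 1], decreasing = TRUE)[1:2]
  sep <- abs(diff(pk)) * img@pixelPitch
  expect_equal(sep, truth@dDia, tolerance = img@pixelPitch)
})

test_that("render records a warning when pixels cannot resolve the wall", {
  truth <- hemoTruth(noiseSd = 0, seed = 1)
  wf <- synthesizeWaveforms(truth)
  img <- renderMMode(wf, pixelPitch = 0.04, speckle = 0)
  expect_match(img@meta$warnings, "too coarse")
})

test_that("Doppler render fills bins up to twice the mean velocity", {
  truth <- hemoTruth(gammaTrue = 0, qAmp = 0, noiseSd = 0, seed = 1)
  wf <- synthesizeWaveforms(truth)
  vConst <- mean(wf@V) * 1e3
  dop <- renderDoppler(wf, vBin = 2, speckle = 0, noiseFloor = 0)
  env <- traceEnvelope(dop)
  expect_equal(env$v_max_mms, rep(2 * vConst, nrow(env)), tolerance = 2)
  expect_equal(env$v_mean_mms, env$v_max_mms / 2)
})

test_that("zero flow gives an empty spectrogram above the noise floor", {
  truth <- hemoTruth(qDia = 0, qAmp = 0, noiseSd = 0, seed = 1)
  wf <- synthesizeWaveforms(truth)
  dop <- renderDoppler(wf, speckle = 0, noiseFloor = 0)
  expect_true(all(intensity(dop) == 0))
  expect_warning(env <- traceEnvelope(dop), "empty spectrogram")
  expect_true(all(env$v_max_mms == 0))
})

test_that("cohort simulation is deterministic and honours planted effects", {
  # zero SDs, zero effects: rows identical within genotype x sex x age x side
  sp <- cohortSpec(nPerGroup = 3, effects = nullEffectTable(),
                   ageTrend = nullAgeTrend(), sdBetween = zeroSdVec(),
                   sdResidual = zeroSdVec(), dropout = FALSE, seed = 1)
  tab <- simulateCohort(sp)$table
  byCell <- split(tab$diameter_mm,
                  paste(tab$genotype, tab$sex, tab$age_days, tab$side))
  expect_true(all(vapply(byCell, function(v) diff(range(v)) == 0, logical(1))))

  # planted +12% diameter, SDs zero: group ratio exactly 1.12
  eff <- data.frame(parameter = "diameter_mm", sex = c("F", "M", "F", "M",
                                                       "F", "M"),
                    age = rep(c(50, 75, 125), each = 2), mult = 1.12)
  sp2 <- cohortSpec(nPerGroup = 3, effects = eff, ageTrend = nullAgeTrend(),
                    sdBetween = zeroSdVec(), sdResidual = zeroSdVec(),
                    dropout = FALSE, seed = 1)
  t2 <- simulateCohort(sp2)$table
  ratio <- mean(t2$diameter_mm[t2$genotype == "dcr"]) /
    mean(t2$diameter_mm[t2$genotype == "control"])
  expect_equal(ratio, 1.12, tolerance = 1e-12)

  # same seed, same table
  expect_identical(simulateCohort(sp2)$table, t2)
})

test_that("planted effects are recovered on average across replicates", {
  eff <- data.frame(parameter = "flow_ml_min", sex = "F",
                    age = c(50, 75, 125), mult = 0.75)
  ratios <- vapply(1:50, function(s) {
    sp <- cohortSpec(nPerGroup = 4, effects = eff, ageTrend = nullAgeTrend(),
                     dropout = FALSE, seed = s)
    tab <- simulateCohort(sp)$table
    f <- tab[tab$sex == "F", ]
    mean(f$flow_ml_min[f$genotype == "dcr"]) /
      mean(f$flow_ml_min[f$genotype == "control"])
  }, numeric(1))
  # Monte-Carlo error of the mean ratio at these SDs is well under 0.03
  expect_equal(mean(ratios), 0.75, tolerance = 0.03)
})

test_that("dropout removes dcr males only at the final age", {
  sp <- cohortSpec(nPerGroup = 6, dropout = TRUE, seed = 42)
  tab <- simulateCohort(sp)$table
  drops <- tab[tab$dropout, ]
  if (nrow(drops) > 0) {
    expect_true(all(drops$genotype == "dcr"))
    expect_true(all(drops$sex == "M"))
    expect_true(all(drops$age_days == 125))
    expect_true(all(is.na(drops$pwv_m_s)))
  }
  succeed()
})
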