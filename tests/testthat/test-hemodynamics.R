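test_that("area/diameter closed forms and scaling laws hold", {
  expect_equal(areaFromDiameter(0.5), 0.19635, tolerance = 1e-4)
  expect_equal(areaFromDiameter(0), 0)
  expect_equal(areaFromDiameter(1) / areaFromDiameter(0.5), 4)
  expect_equal(diameterFromArea(areaFromDiameter(0.437)), 0.437)
})

test_that("flow is the instantaneous area-velocity product in mL/min", {
  fl <- flowWaveform(rep(0.2, 10), rep(100, 10))
  expect_equal(fl$Q_ml_min, rep(1.2, 10))
  expect_equal(fl$meanFlow, 1.2)
  expect_equal(flowWaveform(rep(0.2, 5), rep(0, 5))$Q_ml_min, rep(0, 5))
})

test_that("mean flow through the chain matches the analytic pulse mean", {
  truth <- hemoTruth(gammaTrue = 0, noiseSd = 0, seed = 2)
  m <- chainMetricsDirect(truth)
  expect_equal(m@meanFlow, meanForwardFlow(truth), tolerance = 0.02 * meanForwardFlow(truth))
})

test_that("QA loop recovers the slope exactly for proportional loops", {
  # exact linear-wave pair: A = A0 + q/c, Q = Q0 + q
  c0 <- 3.7
  q <- c(rep(0, 10), 0.5 * (1 - cos(pi * seq(0, 1, length.out = 60))),
         exp(-seq(0, 3, length.out = 130)))
  Q <- 0.3 + q
  A <- 0.16 + (q / 60) / c0  # field-unit slope is 60 c
  fit <- pwvQALoop(Q, A)
  expect_equal(fit$pwv, c0, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_false(fit$negativeSlope)
  expect_gte(fit$n, 4)
})

test_that("QA loop fails on degenerate windows and flags negative slopes", {
  expect_error(pwvQALoop(c(0, 1, 2, 3), c(0, 1, 2, 3)), "window")
  q <- c(seq(0, 1, length.out = 50), seq(1, 0, length.out = 50))
  A <- 0.2 - q / 600  # inverted loop
  fit <- pwvQALoop(0.3 + q, A)
  expect_true(fit$negativeSlope)
  expect_lt(fit$pwv, 0)
})

test_that("PWV estimate is scale-consistent", {
  truth <- hemoTruth(gammaTrue = 0, noiseSd = 0, seed = 2)
  wf <- synthesizeWaveforms(truth)
  A <- wf@A * 1e6; Q <- wf@Q * 6e7
  ift <- which.min(Q[1:which.max(Q)])
  base <- pwvQALoop(Q, A)$pwv
  expect_equal(pwvQALoop(2 * Q, 2 * A)$pwv, base, tolerance = 1e-9)
  expect_equal(pwvQALoop(2 * Q, A)$pwv, 2 * base, tolerance = 1e-9)
})

test_that("wave separation conserves flow and finds planted reflections", {
  # conservation on arbitrary input
  set.seed(3)
  Q <- cumsum(rnorm(100)); A <- 0.2 + cumsum(rnorm(100)) / 50
  dec <- decomposeWaves(Q, A, pwv = 2.4)
  expect_equal(dec$Qf_ml_min + dec$Qr_ml_min, Q, tolerance = 1e-12)

  # reflection-free: Qr identically zero at the true wave speed
  truth <- hemoTruth(gammaTrue = 0, noiseSd = 0, seed = 2)
  wf <- synthesizeWaveforms(truth)
  dec0 <- decomposeWaves(wf@Q * 6e7, wf@A * 1e6, truth@cTrue,
                         qDia = truth@qDia, aDia = aDia(truth))
  expect_lt(max(abs(dec0$Qr_ml_min)), 1e-9 * max(dec0$Qf_ml_min))

  # planted reflection recovered against the generator's ground truth
  truth <- hemoTruth(gammaTrue = 0.3, noiseSd = 0, seed = 2)
  wf <- synthesizeWaveforms(truth)
  dec <- decomposeWaves(wf@Q * 6e7, wf@A * 1e6, truth@cTrue,
                        qDia = truth@qDia, aDia = aDia(truth))
  rmse <- sqrt(mean((dec$Qr_ml_min - wf@Qr * 6e7)^2))
  expect_lt(rmse, 0.03 * truth@qAmp)
})

test_that("reflection coefficient equals the harmonic amplitude ratio", {
  n <- 256
  tt <- seq(0, 1, length.out = n + 1)[1:n]
  for (phi in c(0, 0.7, 2.1, pi, 5)) {
    Qf <- sin(2 * pi * tt)
    Qr <- 0.3 * sin(2 * pi * tt + phi)
    expect_equal(reflectionCoefficient(Qf, Qr)$rc, 0.3, tolerance = 1e-12)
  }
  expect_equal(reflectionCoefficient(sin(2 * pi * tt), rep(0, n))$rc, 0)
  expect_error(reflectionCoefficient(rep(1, n), sin(2 * pi * tt)),
               "first harmonic")
})

test_that("reflection coefficient is invariant to forward amplitude", {
  tallies <- vapply(c(0.7, 1.4, 2.8), function(amp) {
    truth <- hemoTruth(gammaTrue = 0.3, qAmp = amp, qDia = amp / 4,
                       noiseSd = 0, seed = 2)
    chainMetricsDirect(truth)@reflectionCoefficient
  }, numeric(1))
  expect_lt(diff(range(tallies)), 0.01)
  expect_equal(mean(tallies), 0.3, tolerance = 0.02)
})

test_that("pulsatility index follows its definition", {
  expect_equal(pulsatilityIndex(c(10, 60, 35, 30, 25, 20, 10, 10)), 2)
  expect_equal(pulsatilityIndex(rep(7, 20)), 0)
  # half-rectified sinusoid on a baseline: symbolic oracle
  b <- 12; a <- 40
  tt <- seq(0, 1, length.out = 20001)[-20001]
  v <- b + a * pmax(sin(2 * pi * (tt - 0.25)), 0)
  # foot (pre-upstroke minimum) value is b; mean is b + a/pi
  expect_equal(pulsatilityIndex(v, footIndex = 1),
               a / (b + a / pi), tolerance = 1e-3)
})

test_that("Moens-Korteweg modulus matches closed form and scaling", {
  expect_equal(youngsModulus(3, 0.5, 0.05, rho = 1050), 94.5)
  expect_equal(youngsModulus(6, 0.5, 0.05, rho = 1050) /
                 youngsModulus(3, 0.5, 0.05, rho = 1050), 4)
})

test_that("elasticity round-trips through the full waveform chain", {
  E <- 120  # kPa
  D <- 0.45; h <- 0.05; rho <- 1050
  c0 <- sqrt(E * 1000 * h / (rho * D))
  truth <- hemoTruth(cTrue = c0, gammaTrue = 0, dDia = D, hTrue = h,
                     noiseSd = 0, seed = 6)
  m <- chainMetricsDirect(truth)
  expect_equal(m@youngsModulus, E, tolerance = 0.03 * E)
})

test_that("harmonic smoothing preserves linear relations and H1", {
  set.seed(8)
  n <- 256
  x <- cumsum(rnorm(n)); x <- x - mean(x)
  y <- 3 * x + 2
  expect_equal(harmonicSmooth(y, 20), 3 * harmonicSmooth(x, 20) + 2,
               tolerance = 1e-10)
  expect_equal(fft(harmonicSmooth(x, 20))[2], fft(x)[2], tolerance = 1e-10)
  expect_equal(harmonicSmooth(x, Inf), x)
})

test_that("computed vessel metrics populate diagnostics", {
  m <- chainMetricsDirect(hemoTruth(noiseSd = 0, seed = 2))
  expect_true(all(c("qaR2", "qaWindow", "rcReciprocal", "nCyclesUsed") %in%
                    names(m@diagnostics)))
  expect_gt(m@diagnostics$qaR2, 0.99)
  expect_equal(m@diameter, 0.45, tolerance = 0.01)
})
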