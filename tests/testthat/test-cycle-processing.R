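# A periodic pulse train for segmentation tests.
pulseTrain <- function(period = 0.12, nCycles = 8, fs = 5000, noise = 0,
                       seed = 1) {
  set.seed(seed)
  t <- seq(0, nCycles * period, by = 1 / fs)
  phase <- t %% period
  x <- 10 + 50 * ifelse(phase < 0.03, 0.5 * (1 - cos(pi * phase / 0.03)),
                        exp(-(phase - 0.03) / 0.04))
  list(t = t, x = x + rnorm(length(t), 0, noise))
}

test_that("feet of an identical pulse train are spaced by the period", {
  tr <- pulseTrain(period = 0.12, nCycles = 8)
  feet <- detectSystoleFeet(tr$t, tr$x)
  expect_gte(length(feet), 7)
  rr <- diff(feet)
  # interior feet are exact to one sample; the first upstroke only sees a
  # truncated pre-foot context, allow three samples there
  expect_true(all(abs(rr[-1] - 0.12) < 1 / 5000 + 1e-9))
  expect_true(all(abs(rr - 0.12) < 3 / 5000))
})

test_that("constant signals fail foot detection with a diagnostic", {
  t <- seq(0, 1, by = 1e-3)
  expect_error(detectSystoleFeet(t, rep(3, length(t))), "constant")
})

test_that("jittered trains still yield one foot per planted cycle", {
  set.seed(11)
  periods <- 0.12 * (1 + runif(9, -0.08, 0.08))
  starts <- c(0, cumsum(periods))
  t <- seq(0, sum(periods), by = 1 / 5000)
  k <- findInterval(t, starts, rightmost.closed = FALSE)
  phase <- t - starts[pmin(k, length(periods))]
  x <- 10 + 50 * ifelse(phase < 0.03, 0.5 * (1 - cos(pi * phase / 0.03)),
                        exp(-(phase - 0.03) / 0.04))
  feet <- detectSystoleFeet(t, x)
  expect_equal(length(feet), 9)
})

test_that("RR-based arrhythmia rejection follows the 20% rule", {
  feet <- seq(0, 1.2, by = 0.12)
  expect_length(rejectArrhythmic(feet)$rejected, 0)

  feet2 <- c(0, 0.12, 0.24, 0.48, 0.6, 0.72)  # one RR at 2x the median
  rej <- rejectArrhythmic(feet2)
  expect_equal(rej$rejected, 3L)
  expect_equal(rej$retained, c(1L, 2L, 4L, 5L))

  # threshold is configurable
  expect_length(rejectArrhythmic(feet2, tol = 1.5)$rejected, 0)
})

test_that("planted arrhythmic cycles are rejected at the planted rate", {
  set.seed(5)
  nsim <- 40; nCyc <- 12; pArr <- 0.15
  frac <- replicate(nsim, {
    long <- runif(nCyc) < pArr
    rr <- 0.13 * ifelse(long, 1.6, 1) * (1 + runif(nCyc, -0.02, 0.02))
    feet <- c(0, cumsum(rr))
    rej <- rejectArrhythmic(feet)
    length(rej$rejected) / nCyc
  })
  expect_lt(abs(mean(frac) - pArr), 0.05)
})

test_that("ensemble averaging of identical cycles returns the cycle", {
  tr <- pulseTrain(period = 0.12, nCycles = 8)
  feet <- seq(0, 0.96, by = 0.12)
  ens <- ensembleAverage(tr$t, list(x = tr$x), feet, N = 128)
  for (r in seq_len(ens@nUsed)) {
    expect_equal(ens@cycles$x[r, ], meanCycle(ens, "x"), tolerance = 1e-12)
  }
  expect_equal(ens@heartRate, 60 / 0.12, tolerance = 1e-9)
})

test_that("six feet spanning one second give 300 beats per minute", {
  t <- seq(0, 1.05, by = 1e-3)
  x <- sin(2 * pi * t / 0.2)
  ens <- ensembleAverage(t, list(x = x), feet = seq(0, 1, by = 0.2), N = 64)
  expect_equal(ens@heartRate, 300)
  expect_equal(ens@nUsed, 5L)
})

test_that("ensemble mean converges to the template as cycles grow", {
  template <- function(phase) 10 + 50 * exp(-((phase - 0.04) / 0.02)^2)
  rmseFor <- function(nCyc, seed) {
    set.seed(seed)
    period <- 0.12; fs <- 5000
    t <- seq(0, nCyc * period, by = 1 / fs)
    x <- template(t %% period) + rnorm(length(t), 0, 3)
    feet <- seq(0, nCyc * period, by = period)
    feet <- feet[feet <= max(t) - period + 1e-9]
    ens <- ensembleAverage(t, list(x = x), c(feet, max(feet) + period),
                           N = 128)
    phase <- ens@t
    sqrt(mean((meanCycle(ens, "x") - template(phase))^2))
  }
  r4 <- mean(vapply(1:6, function(s) rmseFor(4, s), numeric(1)))
  r32 <- mean(vapply(1:6, function(s) rmseFor(32, s), numeric(1)))
  expect_lt(r32, r4)
  # law of large numbers: roughly 1/sqrt(n)
  expect_equal(r4 / r32, sqrt(32 / 4), tolerance = 0.5)
})

test_that("heart-rate estimates are invariant to time shifts", {
  tr <- pulseTrain(period = 0.12, nCycles = 8)
  f1 <- detectSystoleFeet(tr$t, tr$x)
  f2 <- detectSystoleFeet(tr$t + 37.5, tr$x)
  e1 <- ensembleAverage(tr$t, list(x = tr$x), f1)
  e2 <- ensembleAverage(tr$t + 37.5, list(x = tr$x), f2)
  expect_equal(e1@heartRate, e2@heartRate, tolerance = 1e-9)
})
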