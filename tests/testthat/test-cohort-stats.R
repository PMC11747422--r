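plantedCohort <- function(mult = 1.12, metric = "diameter_mm",
                          sdB = NULL, sdR = NULL, seed = 1, n = 4) {
  eff <- expand.grid(sex = c("F", "M"), age = c(50, 75, 125),
                     stringsAsFactors = FALSE)
  eff$parameter <- metric; eff$mult <- mult
  sp <- cohortSpec(nPerGroup = n, effects = eff, ageTrend = nullAgeTrend(),
                   sexEffect = oneVec(), sideEffect = oneVec(),
                   sdBetween = if (is.null(sdB)) zeroSdVec() else sdB,
                   sdResidual = if (is.null(sdR)) zeroSdVec() else sdR,
                   dropout = FALSE, seed = seed)
  simulateCohort(sp)$table
}

test_that("with zero variability the fitted genotype effect is the plant", {
  tab <- plantedCohort(mult = 1.12)
  fit <- suppressWarnings(suppressMessages(
    fitCohortLmm(tab, "diameter_mm", interactions = character(0))))
  est <- fit@coefficients$estimate[fit@coefficients$term == "genotypedcr"]
  expect_equal(est, 0.12 * 0.42, tolerance = 1e-6)
  expect_true(all(fit@coefficients$p >= 0 & fit@coefficients$p <= 1))
  expect_gte(fit@nObs, fit@nMice)
})

test_that("missing outcomes are dropped listwise, factors validated", {
  sp <- cohortSpec(nPerGroup = 3, dropout = TRUE, seed = 99)
  tab <- simulateCohort(sp)$table
  fit <- fitCohortLmm(tab, "pwv_m_s")
  expect_equal(fit@nObs, sum(!is.na(tab$pwv_m_s)))
  expect_error(fitCohortLmm(tab, "no_such_metric"), "lacks columns")
  oneGeno <- tab[tab$genotype == "dcr", ]
  expect_error(fitCohortLmm(oneGeno, "pwv_m_s"), "levels")
})

test_that("releveling reparameterizes without changing the fit", {
  sp <- cohortSpec(nPerGroup = 4, seed = 17, dropout = FALSE)
  tab <- simulateCohort(sp)$table
  f1 <- fitCohortLmm(tab, "flow_ml_min")
  f2 <- relevelPosthoc(f1, "sex", "M")
  f3 <- relevelPosthoc(f2, "sex", "F")
  expect_equal(f2@logLik, f1@logLik, tolerance = 1e-8)
  expect_equal(f3@coefficients$estimate, f1@coefficients$estimate,
               tolerance = 1e-8)
  expect_false(identical(f1@coefficients$estimate, f2@coefficients$estimate))
})

test_that("releveled simple effects equal group-mean differences", {
  # balanced two-group-per-sex toy data, no within-mouse replication
  set.seed(21)
  df <- expand.grid(rep = 1:2, mouse_id = 1:8,
                    genotype = c("control", "dcr"),
                    sex = c("F", "M"), stringsAsFactors = FALSE)
  df$mouse_id <- paste0(df$genotype, df$sex, df$mouse_id)
  df$age_days <- 50
  df$y <- rnorm(nrow(df)) + ifelse(df$genotype == "dcr" & df$sex == "M", 2, 0)
  fit <- suppressWarnings(suppressMessages(
    fitCohortLmm(df, "y", fixed = c("genotype", "sex"),
                 interactions = "genotype:sex",
                 relevels = list(sex = "M"))))
  est <- fit@coefficients$estimate[fit@coefficients$term == "genotypedcr"]
  gm <- mean(df$y[df$genotype == "dcr" & df$sex == "M"]) -
    mean(df$y[df$genotype == "control" & df$sex == "M"])
  expect_equal(est, gm, tolerance = 1e-6)
})

test_that("AUC equals brute-force Mann-Whitney on random inputs", {
  set.seed(12)
  for (i in 1:30) {
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    v <- round(c(rnorm(n1), rnorm(n2, 1)), 1)  # rounding forces ties
    lab <- rep(c("control", "dcr"), c(n1, n2))
    r <- rocAnalysis(v, lab)
    pos <- v[lab == "dcr"]; neg <- v[lab == "control"]
    u <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(r@auc, max(u, 1 - u), tolerance = 1e-12)
  }
})

test_that("ROC handles separation, permutation null and empty classes", {
  r <- rocAnalysis(c(1, 2, 3, 10, 11, 12), rep(c("control", "dcr"), each = 3))
  expect_equal(r@auc, 1)
  expect_equal(r@youdenJ, 1)
  expect_equal(r@youdenCutoff, 6.5)  # midpoint between the group extremes

  set.seed(4)
  v <- rnorm(2000); lab <- sample(rep(c("control", "dcr"), 1000))
  expect_lt(abs(rocAnalysis(v, lab)@auc - 0.5), 0.05)

  expect_error(rocAnalysis(1:5, rep("dcr", 5)), "two classes")
})

test_that("Youden ties break toward the lower cut-off", {
  # thresholds 2.5 and 6.5 both reach J = 0.5; the lower one must win
  v <- c(1, 5, 4, 8)
  lab <- c("control", "control", "dcr", "dcr")
  r <- rocAnalysis(v, lab)
  expect_equal(r@youdenJ, 0.5)
  expect_equal(r@youdenCutoff, 2.5)
  expect_true(r@youdenCutoff %in% r@thresholds)
})

test_that("the early screen flags a planted female-only flow deficit", {
  eff <- data.frame(parameter = "flow_ml_min", sex = "F",
                    age = c(50, 75, 125), mult = c(0.75, 1, 1))
  sdB <- zeroSdVec(); sdB[] <- 0.04
  sdR <- zeroSdVec(); sdR[] <- 0.03
  sp <- cohortSpec(nPerGroup = 6, effects = eff, ageTrend = nullAgeTrend(),
                   sdBetween = sdB, sdResidual = sdR, dropout = FALSE,
                   seed = 8)
  tab <- simulateCohort(sp)$table
  scr <- screenEarlyBiomarkers(tab, metrics = c("flow_ml_min", "pwv_m_s"))
  flowF <- scr[scr$metric == "flow_ml_min" & scr$sex == "F", ]
  flowM <- scr[scr$metric == "flow_ml_min" & scr$sex == "M", ]
  expect_true(flowF$flagged)
  expect_equal(flowF$direction, "lower")
  expect_gt(flowF$auc, 0.8)
  expect_true(is.finite(flowF$cutoff))
  expect_false(flowM$flagged)
})

test_that("null cohorts false-flag at roughly the nominal rate", {
  flags <- unlist(lapply(1:20, function(s) {
    sp <- cohortSpec(nPerGroup = 6, effects = nullEffectTable(),
                     ageTrend = nullAgeTrend(), dropout = FALSE,
                     seed = 3000 + s)
    tab <- simulateCohort(sp)$table
    scr <- screenEarlyBiomarkers(tab, metrics = c("flow_ml_min", "pwv_m_s"))
    scr$flagged
  }))
  # 80 uncorrected tests at alpha = 0.05: expect about 4 false flags
  expect_lt(mean(flags), 0.15)
})

test_that("pulsatility-heart-rate correlation utility runs", {
  sp <- cohortSpec(nPerGroup = 4, seed = 2, dropout = FALSE)
  tab <- simulateCohort(sp)$table
  ct <- metricCorrelation(tab)
  expect_true(is.numeric(ct$estimate))
  expect_true(ct$p.value >= 0 && ct$p.value <= 1)
})
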