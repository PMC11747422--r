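# Longitudinal cohort statistics: linear mixed-effects models with a mouse
# random intercept, releveled post-hoc contrasts, ROC/AUC with Youden
# cut-offs, and the pre-onset (earliest-age) biomarker screen.

prepCohortData <- function(table, outcome, ageAs, relevels) {
  df <- as.data.frame(table)
  need <- c("mouse_id", "genotype", "sex", "age_days", outcome)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort table lacks columns: ", paste(miss, collapse = ", "))
  df <- df[complete.cases(df[, need, drop = FALSE]), , drop = FALSE]
  df$genotype <- factor(df$genotype, levels = union("control", unique(df$genotype)))
  df$sex <- factor(df$sex, levels = union("F", unique(df$sex)))
  if ("side" %in% names(df))
    df$side <- factor(df$side, levels = union("LCCA", unique(df$side)))
  df$age <- if (ageAs == "factor") factor(df$age_days) else as.numeric(df$age_days)
  for (f in names(relevels)) {
    if (!f %in% names(df)) stop("cannot relevel unknown factor: ", f)
    if (!is.factor(df[[f]])) stop("cannot relevel non-factor: ", f)
    df[[f]] <- relevel(df[[f]], ref = as.character(relevels[[f]]))
  }
  df
}

#' Fit the longitudinal linear mixed-effects model
#'
#' Fits `outcome ~ fixed effects (+ interactions) + (1 | mouse_id)` by
#' restricted maximum likelihood (lme4). Fixed-effect p-values use the
#' Wald normal approximation (z = estimate/SE against N(0,1)); with small
#' mouse-level n this is mildly anti-conservative, which the package's
#' null-calibration simulations make visible rather than hiding behind a
#' degrees-of-freedom recipe.
#'
#' Missing outcome rows (e.g. dropout) are removed listwise before
#' fitting. Age enters as a categorical factor by default (one level per
#' imaging age), or as a continuous covariate with `ageAs = "numeric"`.
#' The body-weight style model without a side factor is obtained with
#' `fixed = c("genotype", "age", "sex")`.
#'
#' @param table cohort table (long format: `mouse_id`, `genotype`, `sex`,
#'   `age_days`, optionally `side`, plus metric columns).
#' @param outcome name of the numeric outcome column.
#' @param fixed main-effect terms; any of "genotype", "age", "sex",
#'   "side".
#' @param interactions interaction terms among the fixed effects, in
#'   formula syntax (e.g. `"genotype:sex"`).
#' @param ageAs `"factor"` or `"numeric"`.
#' @param relevels named list giving a new reference level per factor
#'   (used by [relevelPosthoc()]).
#' @return An [LmmResult-class]. Non-convergence is flagged in
#'   `@converged`, never silently worked around.
#' @export
fitCohortLmm <- function(table, outcome,
                         fixed = c("genotype", "age", "sex", "side"),
                         interactions = c("genotype:age", "age:sex",
                                          "genotype:sex"),
                         ageAs = c("factor", "numeric"),
                         relevels = list()) {
  ageAs <- match.arg(ageAs)
  df <- prepCohortData(table, outcome, ageAs, relevels)
  fixed <- intersect(fixed, c("genotype", "age", "sex", "side"))
  if ("side" %in% fixed && !"side" %in% names(df)) fixed <- setdiff(fixed, "side")
  for (f in setdiff(fixed, "age")) {
    if (nlevels(droplevels(df[[f]])) < 2)
      stop("factor '", f, "' needs at least 2 observed levels")
  }
  rhs <- paste(c(fixed, interactions), collapse = " + ")
  fml <- as.formula(paste0("`", outcome, "` ~ ", rhs, " + (1 | mouse_id)"))

  fit <- lme4::lmer(fml, data = df, REML = TRUE)
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  converged <- length(msgs) == 0 || all(grepl("singular", msgs, ignore.case = TRUE))
  singular <- lme4::isSingular(fit, tol = 1e-5)

  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"], z = sm[, "t value"],
                      stringsAsFactors = FALSE)
  coefs$p <- 2 * pnorm(-abs(coefs$z))
  rownames(coefs) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))

  new("LmmResult", outcome = outcome, coefficients = coefs,
      ranefVar = vc$vcov[vc$grp == "mouse_id"][1],
      sigma2 = vc$vcov[vc$grp == "Residual"][1],
      formula = paste(deparse(fml), collapse = ""),
      nObs = nrow(df), nMice = length(unique(df$mouse_id)),
      logLik = as.numeric(logLik(fit)),
      converged = converged, singular = singular, fit = fit,
      modelData = df,
      callInfo = list(fixed = fixed, interactions = interactions,
                      ageAs = ageAs, relevels = relevels, table = table))
}

#' Post-hoc contrasts by releveling
#'
#' Refits the model with a different reference level for one factor, so
#' that simple (within-level) effects — for instance the genotype effect
#' within males at the first imaging age — appear directly in the
#' coefficient table. Releveling is a reparameterization of the same
#' model: the restricted log-likelihood and fit quality are unchanged.
#'
#' @param result an [LmmResult-class] from [fitCohortLmm()].
#' @param factor factor to relevel ("genotype", "sex", "side" or "age"
#'   when age is categorical).
#' @param ref new reference level.
#' @return A new [LmmResult-class].
#' @export
relevelPosthoc <- function(result, factor, ref) {
  stopifnot(is(result, "LmmResult"))
  ci <- result@callInfo
  rl <- ci$relevels
  rl[[factor]] <- ref
  fitCohortLmm(ci$table, result@outcome, fixed = ci$fixed,
               interactions = ci$interactions, ageAs = ci$ageAs,
               relevels = rl)
}

#' Empirical ROC curve, AUC and Youden cut-off
#'
#' Builds the empirical ROC of a continuous marker against a two-class
#' label (pROC: thresholds are the midpoints between sorted unique marker
#' values plus the two infinities; the AUC is the trapezoidal area, which
#' equals the normalized Mann-Whitney statistic). The orientation is
#' chosen automatically so AUC >= 0.5 and recorded. The optimal cut-off
#' maximizes the Youden index J = sensitivity + specificity - 1, with
#' ties broken toward the lower cut-off.
#'
#' @param values numeric marker values.
#' @param labels class labels (factor or character, exactly two classes
#'   present).
#' @param positive label treated as the diseased/positive class.
#' @return A [RocResult-class]. Errors if either class is empty.
#' @export
rocAnalysis <- function(values, labels, positive = "dcr") {
  labels <- as.character(labels)
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  classes <- unique(labels)
  if (!positive %in% classes)
    stop("positive class '", positive, "' absent from the labels")
  negative <- setdiff(classes, positive)
  if (length(negative) != 1)
    stop("labels must contain exactly two classes (one may be empty): got ",
         paste(classes, collapse = ", "))
  if (sum(labels == positive) == 0 || sum(labels == negative) == 0)
    stop("both classes must be non-empty")

  r <- pROC::roc(response = labels, predictor = values,
                 levels = c(negative, positive), direction = "<",
                 quiet = TRUE)
  if (as.numeric(r$auc) < 0.5)
    r <- pROC::roc(response = labels, predictor = values,
                   levels = c(negative, positive), direction = ">",
                   quiet = TRUE)
  J <- r$sensitivities + r$specificities - 1
  jmax <- max(J)
  best <- which(J >= jmax - 1e-12)
  cutoff <- min(r$thresholds[best])

  new("RocResult", thresholds = r$thresholds,
      sensitivity = r$sensitivities, specificity = r$specificities,
      auc = as.numeric(r$auc), youdenCutoff = cutoff, youdenJ = jmax,
      direction = r$direction, positiveClass = positive)
}

#' Screen for pre-onset (earliest-age) biomarkers, per sex
#'
#' Restricts attention to the earliest imaging age and asks, separately
#' for each sex, which metrics already separate the genotypes before
#' disease onset. The genotype simple effect within (sex, earliest age)
#' is read from the releveled full mixed model (default route) or from a
#' per-sex stratified refit (`stratified = TRUE`). Metrics significant at
#' `alpha` are passed to [rocAnalysis()] on the per-mouse side-averaged
#' values at the earliest age. No multiplicity correction is applied by
#' default; `adjust = "BH"` switches on Benjamini-Hochberg within the
#' screen.
#'
#' @param table cohort table (see [fitCohortLmm()]).
#' @param metrics metric columns to screen (default all eight).
#' @param alpha significance level for flagging.
#' @param interactions interaction structure of the full model; the
#'   default includes the three-way term so the releveled genotype
#'   coefficient is the simple effect at the reference (sex, age).
#' @param stratified fit per-sex models instead of releveling the full
#'   model.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with one row per (sex, metric): the genotype simple
#'   effect estimate and p-value, `flagged`, effect `direction`
#'   ("higher"/"lower" in dcr), and for flagged metrics the `auc` and
#'   Youden `cutoff`.
#' @export
screenEarlyBiomarkers <- function(table, metrics = cohortMetricNames(),
                                  alpha = 0.05,
                                  interactions = c("genotype:age", "age:sex",
                                                   "genotype:sex",
                                                   "genotype:age:sex"),
                                  stratified = FALSE, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  df <- as.data.frame(table)
  metrics <- intersect(metrics, names(df))
  if (!length(metrics)) stop("no metric columns found in the table")
  firstAge <- min(df$age_days, na.rm = TRUE)

  out <- list()
  for (m in metrics) {
    for (sx in c("F", "M")) {
      est <- p <- NA_real_
      fitOk <- tryCatch({
        if (stratified) {
          sub <- df[df$sex == sx, , drop = FALSE]
          fit <- fitCohortLmm(sub, m, fixed = c("genotype", "age", "side"),
                              interactions = "genotype:age",
                              relevels = list(age = firstAge))
        } else {
          fit <- fitCohortLmm(df, m, interactions = interactions,
                              relevels = list(age = firstAge, sex = sx))
        }
        row <- fit@coefficients[fit@coefficients$term == "genotypedcr", ]
        est <- row$estimate; p <- row$p
        TRUE
      }, error = function(e) FALSE)
      if (!isTRUE(fitOk)) { est <- NA_real_; p <- NA_real_ }
      out[[paste(m, sx)]] <- data.frame(
        sex = sx, metric = m, estimate = est, p = p,
        stringsAsFactors = FALSE)
    }
  }
  rep <- do.call(rbind, out)
  rownames(rep) <- NULL
  if (adjust == "BH") rep$p <- stats::p.adjust(rep$p, method = "BH")
  rep$flagged <- !is.na(rep$p) & rep$p < alpha
  rep$direction <- ifelse(is.na(rep$estimate), NA_character_,
                          ifelse(rep$estimate > 0, "higher", "lower"))
  rep$auc <- NA_real_
  rep$cutoff <- NA_real_

  first <- df[df$age_days == firstAge & !is.na(df$age_days), , drop = FALSE]
  for (i in which(rep$flagged)) {
    sub <- first[first$sex == rep$sex[i], , drop = FALSE]
    perMouse <- aggregate(sub[[rep$metric[i]]],
                          by = list(mouse_id = sub$mouse_id,
                                    genotype = sub$genotype),
                          FUN = mean, na.rm = TRUE)
    roc <- tryCatch(rocAnalysis(perMouse$x, perMouse$genotype), error = function(e) NULL)
    if (!is.null(roc)) {
      rep$auc[i] <- roc@auc
      rep$cutoff[i] <- roc@youdenCutoff
    }
  }
  rep
}

#' Simple correlation utility (e.g. pulsatility index vs heart rate)
#'
#' @param table cohort table.
#' @param x,y metric column names.
#' @param method correlation method passed to [stats::cor.test()].
#' @return htest object from `cor.test` on complete cases.
#' @export
metricCorrelation <- function(table, x = "pulsatility_index",
                              y = "heart_rate_bpm", method = "pearson") {
  df <- as.data.frame(table)
  ok <- complete.cases(df[, c(x, y)])
  stats::cor.test(df[[x]][ok], df[[y]][ok], method = method)
}
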