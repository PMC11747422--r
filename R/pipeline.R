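# Pipeline orchestration: simulate -> extract -> analyze -> stats, with a
# manifest, per-stage seeds and full determinism under a fixed global seed.

configError <- function(...) {
  stop(structure(class = c("carotidwave_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Default pipeline configuration
#'
#' The demo configuration mirrors the study design the package models:
#' 6 mice per genotype-by-sex cell imaged at 50, 75 and 125 days on both
#' carotids, full image rendering and extraction, 256 samples per
#' resampled cycle and a 20% RR rejection tolerance.
#'
#' @param seed global seed; every stochastic stage derives its own seed
#'   from it.
#' @param outdir output directory (set at [runPipeline()] time if NULL).
#' @return Nested configuration list (YAML-serializable).
#' @export
defaultRunConfig <- function(seed = 1, outdir = NULL) {
  list(
    seed = seed,
    outdir = outdir,
    stages = list(simulate = TRUE, extract = TRUE, analyze = TRUE,
                  stats = TRUE),
    cohort = list(n_per_group = 6, ages = c(50, 75, 125), dropout = TRUE),
    synth = list(n_cycles = 20, fs = 5000),
    mmode = list(pixel_pitch_mm = 0.01, line_rate_hz = 1000, speckle = 0.5),
    doppler = list(v_bin_mm_s = 5, line_rate_hz = 1000, speckle = 0.5,
                   noise_floor = 0.05),
    cycles = list(n_samples = 256, rr_tol = 0.2),
    stats = list(alpha = 0.05, age_as = "factor"),
    write_images = FALSE,
    write_waveforms = FALSE,
    log_level = "info"
  )
}

#' Read and validate a pipeline configuration from YAML
#'
#' Unknown keys and unknown stage names are configuration errors (the CLI
#' maps them to exit code 2). Values omitted from the file keep their
#' defaults. The configuration round-trips through YAML unchanged.
#'
#' @param path YAML file.
#' @param seed optional override of the file's seed.
#' @return Validated configuration list.
#' @export
readRunConfig <- function(path, seed = NULL) {
  if (!file.exists(path)) configError("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(defaultRunConfig(), user)
  if (!is.null(seed)) cfg$seed <- seed
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg configuration list to validate.
#' @export
validateRunConfig <- function(cfg) {
  known <- names(defaultRunConfig())
  extra <- setdiff(names(cfg), known)
  if (length(extra)) configError("unknown config keys: ", paste(extra, collapse = ", "))
  badStage <- setdiff(names(cfg$stages), c("simulate", "extract", "analyze", "stats"))
  if (length(badStage)) configError("unknown stages: ", paste(badStage, collapse = ", "))
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || !is.finite(cfg$seed))
    configError("seed must be a finite number")
  for (f in c("n_per_group")) if (cfg$cohort[[f]] < 2)
    configError("cohort n_per_group must be >= 2")
  if (any(diff(cfg$cohort$ages) <= 0)) configError("cohort ages must increase")
  if (cfg$synth$n_cycles < 3) configError("synth n_cycles must be >= 3")
  cfg
}

# Deterministic per-stage seed derived from the global seed; stays well
# below 2^31.
stageSeed <- function(seed, stage) {
  (as.integer(seed %% 1e6) * 1009L + sum(utf8ToInt(stage))) %% 2147483647L
}

pipeLog <- function(state, level, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (levels[[level]] < levels[[state$logLevel]]) return(invisible())
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"),
                  toupper(level), paste0(...))
  message(line)
  if (!is.null(state$logFile)) cat(line, "\n", file = state$logFile,
                                   append = TRUE)
  invisible()
}

#' Analyze one recording through the measurement chain
#'
#' Synthesizes waveforms from a truth, optionally renders and re-extracts
#' M-mode and Doppler images, segments cycles on the velocity signal and
#' computes the full [VesselMetrics-class]. With `extract = FALSE` the
#' generator's waveforms feed the cycle stage directly (used for
#' stage-equivalence checks and fast runs).
#'
#' @param truth a [HemoTruth-class].
#' @param config pipeline configuration (for the synth/mmode/doppler/
#'   cycles blocks).
#' @param extract render images and extract traces (TRUE) or use the
#'   waveforms directly (FALSE).
#' @param side side label carried into the metrics.
#' @return list: `metrics` ([VesselMetrics-class]), `ensemble`, `waveforms`.
#' @export
analyzeRecording <- function(truth, config = defaultRunConfig(),
                             extract = TRUE, side = NA_character_) {
  wf <- synthesizeWaveforms(truth, nCycles = config$synth$n_cycles,
                            fs = config$synth$fs)
  rseed <- if (is.na(truth@seed)) NA else (truth@seed + 13) %% 2147483647

  if (extract) {
    mm <- renderMMode(wf, pixelPitch = config$mmode$pixel_pitch_mm,
                      lineRate = config$mmode$line_rate_hz,
                      speckle = config$mmode$speckle, seed = rseed)
    dop <- renderDoppler(wf, vBin = config$doppler$v_bin_mm_s,
                         lineRate = config$doppler$line_rate_hz,
                         speckle = config$doppler$speckle,
                         noiseFloor = config$doppler$noise_floor,
                         seed = if (is.na(rseed)) NA else rseed + 1)
    walls <- outlineWalls(mm)
    env <- traceEnvelope(dop)
    n <- min(nrow(walls), nrow(env))
    t <- walls$t_s[seq_len(n)]
    signals <- list(
      area = areaFromDiameter(walls$diameter_mm[seq_len(n)]),
      velocity = env$v_mean_mms[seq_len(n)],
      thickness = (walls$near_thickness_mm + walls$far_thickness_mm)[seq_len(n)] / 2)
  } else {
    t <- wf@t
    signals <- list(area = m2ToMm2(wf@A), velocity = mToMm(wf@V),
                    thickness = rep(truth@hTrue, length(t)))
  }

  feet <- detectSystoleFeet(t, signals$velocity)
  ens <- ensembleAverage(t, signals, feet, N = config$cycles$n_samples,
                         tol = config$cycles$rr_tol)
  metrics <- computeVesselMetrics(ens, side = side)
  list(metrics = metrics, ensemble = ens, waveforms = wf)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order (simulate, extract+analyze,
#' stats), writing every intermediate artifact and a JSON manifest
#' (inputs, outputs, configuration and its hash, package version) to the
#' output directory. Identical configuration and seed give byte-identical
#' metric CSVs. A stage failure halts the run with the failing stage
#' named; artifacts written so far are retained.
#'
#' @param config configuration list from [defaultRunConfig()] or
#'   [readRunConfig()].
#' @param outdir output directory (overrides `config$outdir`).
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
runPipeline <- function(config = defaultRunConfig(), outdir = NULL) {
  config <- validateRunConfig(config)
  outdir <- outdir %||% config$outdir
  if (is.null(outdir)) configError("an output directory is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  state <- list(logLevel = config$log_level %||% "info",
                logFile = file.path(outdir, "run.log"))

  manifest <- list(package = "carotidwave",
                   version = as.character(packageVersion("carotidwave")),
                   created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   seed = config$seed, config = config,
                   config_hash = rlang::hash(config),
                   stages_run = character(0), files = list())
  saveManifest <- function() {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  runStage <- function(name, fun) {
    pipeLog(state, "info", "stage ", name, " started")
    res <- tryCatch(fun(), error = function(e) {
      saveManifest()
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages_run <<- c(manifest$stages_run, name)
    pipeLog(state, "info", "stage ", name, " done")
    res
  }

  sim <- NULL
  if (isTRUE(config$stages$simulate)) {
    sim <- runStage("simulate", function() {
      spec <- cohortSpec(nPerGroup = config$cohort$n_per_group,
                         ages = config$cohort$ages,
                         dropout = config$cohort$dropout,
                         seed = stageSeed(config$seed, "simulate"))
      s <- simulateCohort(spec)
      writeCohortCSV(s$table, file.path(outdir, "cohort_true_metrics.csv"))
      s
    })
    manifest$files$cohort_true_metrics <- "cohort_true_metrics.csv"
  }

  measured <- NULL
  if (isTRUE(config$stages$analyze)) {
    if (is.null(sim)) stop("stage 'analyze' failed: no simulated cohort available")
    measured <- runStage("analyze", function() {
      tab <- sim$table
      rows <- list()
      failures <- 0L
      decompWritten <- FALSE
      for (i in seq_len(nrow(tab))) {
        if (isTRUE(tab$dropout[i])) next
        key <- paste(tab$mouse_id[i], tab$age_days[i], tab$side[i], sep = "/")
        truth <- sim$truths[[key]]
        res <- tryCatch(
          analyzeRecording(truth, config,
                           extract = isTRUE(config$stages$extract),
                           side = tab$side[i]),
          error = function(e) e)
        if (inherits(res, "error")) {
          failures <- failures + 1L
          pipeLog(state, "warn", "recording ", key, " failed: ",
                  conditionMessage(res))
          next
        }
        if (isTRUE(config$write_images) && isTRUE(config$stages$extract)) {
          stem <- gsub("/", "_", key)
          writeMModeTIFF(renderMMode(res$waveforms,
                                     pixelPitch = config$mmode$pixel_pitch_mm,
                                     lineRate = config$mmode$line_rate_hz,
                                     speckle = config$mmode$speckle,
                                     seed = (truth@seed + 13) %% 2147483647),
                         file.path(outdir, paste0(stem, "_mmode.tiff")))
        }
        if (isTRUE(config$write_waveforms)) {
          stem <- gsub("/", "_", key)
          writeWaveformCSV(res$waveforms,
                           file.path(outdir, paste0(stem, "_waveforms.csv")))
        }
        if (!decompWritten) {
          mc <- res$metrics@diagnostics$meanCycle
          write.csv(data.frame(t_s = mc$t, Q_ml_min = mc$Q,
                               Qf_ml_min = mc$Qf, Qr_ml_min = mc$Qr),
                    file.path(outdir, "decomposition_example.csv"),
                    row.names = FALSE)
          decompWritten <- TRUE
        }
        rows[[key]] <- cbind(
          tab[i, c("mouse_id", "genotype", "sex", "age_days")],
          metricsRow(res$metrics))
      }
      if (!length(rows)) stop("every recording failed")
      if (failures > 0)
        pipeLog(state, "warn", failures, " recording(s) failed and were skipped")
      m <- do.call(rbind, rows)
      rownames(m) <- NULL
      writeCohortCSV(m, file.path(outdir, "measured_metrics.csv"))
      m
    })
    manifest$files$measured_metrics <- "measured_metrics.csv"
    manifest$files$decomposition_example <- "decomposition_example.csv"
  }

  if (isTRUE(config$stages$stats)) {
    runStage("stats", function() {
      tab <- measured %||% sim$table
      fits <- lapply(cohortMetricNames(), function(m) {
        tryCatch(fitCohortLmm(tab, m), error = function(e) NULL)
      })
      names(fits) <- cohortMetricNames()
      coefTab <- do.call(rbind, lapply(names(fits), function(m) {
        if (is.null(fits[[m]])) return(NULL)
        cbind(outcome = m, fits[[m]]@coefficients)
      }))
      write.csv(coefTab, file.path(outdir, "lmm_summary.csv"),
                row.names = FALSE)
      screen <- screenEarlyBiomarkers(tab, alpha = config$stats$alpha)
      write.csv(screen, file.path(outdir, "screening_report.csv"),
                row.names = FALSE)

      con <- file(file.path(outdir, "report.txt"), "w")
      on.exit(close(con))
      writeLines(c(
        sprintf("carotidwave run (seed %s)", config$seed),
        sprintf("recordings analyzed: %s",
                if (is.null(measured)) "metric-level only" else nrow(measured)),
        "", "Pre-onset (earliest age) biomarker screen:",
        utils::capture.output(print(screen, row.names = FALSE))), con)
      NULL
    })
    manifest$files$lmm_summary <- "lmm_summary.csv"
    manifest$files$screening_report <- "screening_report.csv"
    manifest$files$report <- "report.txt"
  }

  manifest$files$log <- "run.log"
  saveManifest()
  manifest$outdir <- outdir
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summary figures from a pipeline run
#'
#' Longitudinal mean +/- SEM panels per metric, split by genotype and sex
#' and faceted by side (one PDF per metric), plus the forward/reflected
#' decomposition overlay of a representative recording annotated with the
#' conservation residual `max |Q - (Q_f + Q_r)|`.
#'
#' @param manifest a manifest from [runPipeline()], or the path to a run
#'   directory / `manifest.json`.
#' @param outdir where to write the figures (default: the run directory).
#' @return Character vector of figure paths, invisibly.
#' @export
makeFigures <- function(manifest, outdir = NULL) {
  if (is.character(manifest)) {
    dirPath <- if (grepl("manifest\\.json$", manifest)) dirname(manifest) else manifest
    mf <- file.path(dirPath, "manifest.json")
    if (!file.exists(mf)) stop("no manifest.json found in ", dirPath)
    manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
    manifest$outdir <- dirPath
  }
  run <- manifest$outdir
  outdir <- outdir %||% run
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  metricsPath <- file.path(run, manifest$files$measured_metrics %||%
                                  "measured_metrics.csv")
  if (!file.exists(metricsPath))
    metricsPath <- file.path(run, "cohort_true_metrics.csv")
  if (!file.exists(metricsPath))
    stop("missing metric table: expected measured_metrics.csv or ",
         "cohort_true_metrics.csv in ", run)
  tab <- readCohortCSV(metricsPath)
  tab <- tab[complete.cases(tab[, intersect(cohortMetricNames(), names(tab))]), ]
  if (!nrow(tab)) stop("metric table ", metricsPath, " has no complete rows")

  paths <- character(0)
  for (m in intersect(cohortMetricNames(), names(tab))) {
    agg <- aggregate(tab[[m]],
                     by = list(genotype = tab$genotype, sex = tab$sex,
                               side = tab$side, age_days = tab$age_days),
                     FUN = function(x) c(mean = mean(x),
                                         sem = sd(x) / sqrt(length(x))))
    agg <- cbind(agg[, 1:4], as.data.frame(agg$x))
    p <- ggplot2::ggplot(agg, ggplot2::aes(
           x = .data$age_days, y = .data$mean,
           color = .data$genotype, linetype = .data$sex)) +
      ggplot2::geom_line() +
      ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                            ymax = .data$mean + .data$sem)) +
      ggplot2::facet_wrap(~side) +
      ggplot2::labs(x = "age (days)", y = m,
                    title = paste("Longitudinal", m, "(mean +/- SEM)")) +
      ggplot2::theme_bw()
    f <- file.path(outdir, paste0("fig_", m, ".pdf"))
    ggplot2::ggsave(f, p, width = 7, height = 4)
    paths <- c(paths, f)
  }

  decompPath <- file.path(run, "decomposition_example.csv")
  if (file.exists(decompPath)) {
    d <- read.csv(decompPath)
    resid <- max(abs(d$Q_ml_min - (d$Qf_ml_min + d$Qr_ml_min)))
    dl <- rbind(
      data.frame(t = d$t_s, Q = d$Q_ml_min, wave = "observed Q"),
      data.frame(t = d$t_s, Q = d$Qf_ml_min, wave = "forward Q_f"),
      data.frame(t = d$t_s, Q = d$Qr_ml_min, wave = "reflected Q_r"))
    p <- ggplot2::ggplot(dl, ggplot2::aes(.data$t, .data$Q,
                                          color = .data$wave)) +
      ggplot2::geom_line() +
      ggplot2::scale_color_manual(values = c("observed Q" = "black",
                                             "forward Q_f" = "red",
                                             "reflected Q_r" = "blue")) +
      ggplot2::labs(x = "time from foot (s)", y = "flow (mL/min)",
                    title = "Forward/reflected wave decomposition",
                    subtitle = sprintf("max |Q - (Q_f + Q_r)| = %.2e mL/min",
                                       resid)) +
      ggplot2::theme_bw()
    f <- file.path(outdir, "fig_decomposition.pdf")
    ggplot2::ggsave(f, p, width = 7, height = 4)
    paths <- c(paths, f)
  }
  invisible(paths)
}
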