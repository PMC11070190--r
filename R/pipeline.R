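#' Build a pipeline run configuration
#'
#' Assembles the configuration consumed by \code{\link{runPipeline}}:
#' which stages to run, the simulation and segmentation settings, the mass
#' balance inputs, and one global seed fanned out deterministically to
#' every stochastic stage.
#'
#' @param outDir run directory (created if absent).
#' @param stages subset of
#'   \code{c("simulate", "segment", "quantify", "transfer")}; later stages
#'   require earlier ones.
#' @param nCells labeled cells to simulate.
#' @param nControls unlabeled control cells for calibration.
#' @param sim list of \code{\link{SimConfig}} arguments (seed is supplied
#'   by the pipeline).
#' @param segParams list of \code{\link{segmentationParams}} arguments.
#' @param volumeRatio diazoplast:host(N) volume ratio for the mass balance.
#' @param bootstrapB bootstrap resamples for the transfer CI.
#' @param seed global integer seed.
#' @param writeImages also write the simulated rasters (text format).
#' @return a run-config list.
#' @export
runConfig <- function(outDir, stages = c("simulate", "segment", "quantify",
                                         "transfer"),
                      nCells = 100L, nControls = 50L, sim = list(),
                      segParams = list(), volumeRatio = 0.06,
                      bootstrapB = 1000L, seed = 1L, writeImages = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  need <- c("simulate", "segment", "quantify", "transfer")
  ord <- match(stages, need)
  if (any(diff(sort(ord)) > 1) || !1 %in% ord)
    stop("stages must form a prefix of simulate > segment > quantify > transfer")
  list(outDir = outDir, stages = stages, nCells = as.integer(nCells),
       nControls = as.integer(nControls), sim = sim, segParams = segParams,
       volumeRatio = volumeRatio, bootstrapB = as.integer(bootstrapB),
       seed = as.integer(seed), writeImages = isTRUE(writeImages))
}

#' Load a run configuration from YAML
#' @param path YAML file with \code{runConfig} fields.
#' @return a run-config list.
#' @export
runConfigFromYaml <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(runConfig, y)
}

groundTruthTable <- function(pop) {
  do.call(rbind, lapply(pop, function(cell) {
    t <- cell$truth
    classes <- setdiff(names(COMPARTMENT_CODES), "background")
    data.frame(cell_id = t@cellId, class = classes,
               atom15N_true = 100 * t@atom15N[classes],
               atom13C_true = 100 * t@atom13C[classes],
               volume_um3 = t@volumes[classes],
               active = t@active, active_c = t@activeC,
               row.names = NULL)
  }))
}

segmentAndQuantify <- function(pop, segParams, logLine) {
  quants <- list()
  for (cell in pop) {
    id <- cell$truth@cellId
    q <- tryCatch({
      m <- segmentCell(cell$image, segParams)
      cm <- segmentCompartments(cell$image, m, segParams)
      quantifyRois(cell$image, cm, cellId = id)
    }, error = function(e) {
      logLine(sprintf("cell %d skipped: %s", id, conditionMessage(e)))
      NULL
    })
    if (!is.null(q)) quants[[length(quants) + 1L]] <- q
  }
  do.call(rbind, quants)
}

#' Run the simulate - segment - quantify - transfer pipeline
#'
#' Executes the configured stages into a run directory, producing
#' \code{quants.csv} (labeled-cell ROI quantifications),
#' \code{control_quants.csv}, \code{activity.json} (active-cell fractions
#' and isotope co-classification), \code{transfer.json} (slope, R-squared
#' and transfer fraction with bootstrap CI), \code{manifest.yaml}
#' (configuration, seed, package version, per-stage status and output
#' checksums) and \code{log.txt}. Reruns with the same configuration and
#' seed reproduce the deterministic outputs bit-identically.
#'
#' @param config list from \code{\link{runConfig}} or
#'   \code{\link{runConfigFromYaml}}.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(config$outDir, "log.txt")
  logCon <- file(logPath, open = "wt")
  on.exit(close(logCon))
  logLine <- function(msg)
    writeLines(paste(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), msg), logCon)

  status <- list()
  seeds <- fanOutSeeds(config$seed, 4L)
  runStage <- function(name, fn) {
    if (!name %in% config$stages) return(invisible(NULL))
    logLine(paste("stage start:", name))
    tryCatch(fn(), error = function(e) {
      status[[name]] <<- paste("failed:", conditionMessage(e))
      writeManifest(config, status, logLine)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  writeManifest <- function(config, status, logLine) {
    outs <- list.files(config$outDir, full.names = TRUE, recursive = TRUE)
    outs <- outs[!basename(outs) %in% c("manifest.yaml", "log.txt")]
    md5 <- as.list(tools::md5sum(outs))
    names(md5) <- substring(outs, nchar(config$outDir) + 2L)
    manifest <- list(
      package_version = as.character(utils::packageVersion("symbiotrace")),
      seed = config$seed,
      stages = as.list(config$stages),
      n_cells = config$nCells, n_controls = config$nControls,
      volume_ratio = config$volumeRatio, bootstrap_B = config$bootstrapB,
      sim = config$sim, seg_params = config$segParams,
      stage_status = status, output_md5 = md5)
    yaml::write_yaml(manifest, file.path(config$outDir, "manifest.yaml"))
    manifest
  }

  pop <- controls <- NULL
  runStage("simulate", function() {
    simArgs <- config$sim
    simArgs$seed <- seeds[1]
    simCfg <- do.call(SimConfig, simArgs)
    pop <<- simulatePopulation(simCfg, config$nCells)
    ctrlArgs <- simArgs
    ctrlArgs$fracActive <- 0; ctrlArgs$fracFixingC <- 0
    ctrlArgs$seed <- seeds[2]
    controls <<- simulatePopulation(do.call(SimConfig, ctrlArgs),
                                    config$nControls)
    utils::write.csv(groundTruthTable(pop),
                     file.path(config$outDir, "ground_truth.csv"),
                     row.names = FALSE)
    if (config$writeImages || identical(config$stages, "simulate")) {
      imgDir <- file.path(config$outDir, "images")
      dir.create(imgDir, showWarnings = FALSE)
      for (cell in pop)
        writeIonImage(cell$image,
                      file.path(imgDir, sprintf("cell_%03d",
                                                cell$truth@cellId)),
                      format = "text")
    }
    status[["simulate"]] <<- "ok"
  })

  quants <- ctrlQuants <- NULL
  runStage("segment", function() {
    segP <- do.call(segmentationParams, config$segParams)
    quants <<- segmentAndQuantify(pop, segP, logLine)
    ctrlQuants <<- segmentAndQuantify(controls, segP, logLine)
    if (is.null(quants) || is.null(ctrlQuants))
      stop("segmentation produced no usable cells")
    writeRoiTable(quants, file.path(config$outDir, "quants.csv"))
    writeRoiTable(ctrlQuants, file.path(config$outDir,
                                        "control_quants.csv"))
    status[["segment"]] <<- "ok"
  })

  cal15 <- cal13 <- NULL
  runStage("quantify", function() {
    cal15 <<- calibrateNaturalAbundance(ctrlQuants, "15N")
    cal13 <<- calibrateNaturalAbundance(ctrlQuants, "13C")
    act <- activitySummary(quants, cal15, cal13)
    jsonlite::write_json(list(
      n_cells = act$n_cells,
      fraction_active = act$fraction_active,
      fraction_fixing_c = act$fraction_fixing_c,
      co_classification = if (!is.null(act$co_classification))
        as.list(as.data.frame(act$co_classification)) else NULL,
      calibration_15N = list(mean = cal15@mean, sd = cal15@sd,
                             threshold = cal15@threshold),
      calibration_13C = list(mean = cal13@mean, sd = cal13@sd,
                             threshold = cal13@threshold)),
      file.path(config$outDir, "activity.json"), auto_unbox = TRUE,
      digits = NA)
    status[["quantify"]] <<- "ok"
  })

  runStage("transfer", function() {
    cells <- cellRecords(quants, cal15)
    est <- bootstrapTransfer(cells, config$volumeRatio,
                             B = config$bootstrapB, seed = seeds[3])
    jsonlite::write_json(list(
      slope = est@slope, r2 = est@r2, volume_ratio = est@volumeRatio,
      transfer_fraction = est@transferFraction,
      ci_low = est@ciLow, ci_high = est@ciHigh,
      n_cells = est@nCells, n_bootstrap = est@nBootstrap,
      seed = est@seed),
      file.path(config$outDir, "transfer.json"), auto_unbox = TRUE,
      digits = NA)
    status[["transfer"]] <<- "ok"
  })

  logLine("run complete")
  invisible(writeManifest(config, status, logLine))
}

#' Summarize a pipeline run directory
#'
#' Collects every number needed to compare a run against reported values:
#' per-compartment atom percent means, active-cell fractions, calibration
#' thresholds, and the transfer estimate. Missing stage outputs are listed
#' as absent rather than raising an error.
#'
#' @param runDir directory written by \code{\link{runPipeline}}.
#' @return character vector of report lines (also printed).
#' @export
makeReport <- function(runDir) {
  lines <- c("symbiotrace run report", paste("run directory:", runDir), "")
  qp <- file.path(runDir, "quants.csv")
  if (file.exists(qp)) {
    q <- readRoiTable(qp)
    lines <- c(lines, "per-compartment atom% (labeled cells):")
    for (cls in unique(q$class)) {
      sub <- q[q$class == cls, ]
      lines <- c(lines, sprintf(
        "  %-12s n=%4d  15N %.4f%%  13C %.4f%%", cls, nrow(sub),
        mean(sub$atom15N, na.rm = TRUE), mean(sub$atom13C, na.rm = TRUE)))
    }
  } else lines <- c(lines, "quants.csv: absent")
  ap <- file.path(runDir, "activity.json")
  if (file.exists(ap)) {
    act <- jsonlite::read_json(ap, simplifyVector = TRUE)
    lines <- c(lines, sprintf(
      "fraction of cells with active diazoplasts: %.3f [%.3f, %.3f] (n=%d)",
      act$fraction_active$estimate, act$fraction_active$lower,
      act$fraction_active$upper, act$fraction_active$n))
    if (!is.null(act$fraction_fixing_c))
      lines <- c(lines, sprintf(
        "fraction of cells fixing carbon: %.3f [%.3f, %.3f]",
        act$fraction_fixing_c$estimate, act$fraction_fixing_c$lower,
        act$fraction_fixing_c$upper))
    lines <- c(lines, sprintf(
      "15N calibration: mean %.4f%%, threshold %.4f%%",
      act$calibration_15N$mean, act$calibration_15N$threshold))
  } else lines <- c(lines, "activity.json: absent")
  tp <- file.path(runDir, "transfer.json")
  if (file.exists(tp)) {
    tr <- jsonlite::read_json(tp, simplifyVector = TRUE)
    lines <- c(lines, sprintf(
      "host-vs-diazoplast slope: %.3f (R2 = %.3f)", tr$slope, tr$r2),
      sprintf("transfer fraction at volume ratio %.3f: %.3f [%.3f, %.3f]",
              tr$volume_ratio, tr$transfer_fraction, tr$ci_low, tr$ci_high))
  } else lines <- c(lines, "transfer.json: absent")
  cat(lines, sep = "\n")
  invisible(lines)
}
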