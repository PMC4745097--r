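# End-to-end orchestration with config, manifest and reproducible seeds.

#' Assemble a pipeline configuration
#'
#' Bundles every stage's parameter block plus a global seed. Each block is
#' validated by its own constructor; unknown keys are rejected.
#'
#' @param sim \code{\link{simParams}} for simulate mode.
#' @param registration \code{\link{registrationParams}}.
#' @param detection \code{\link{detectionParams}}.
#' @param merge \code{\link{mergeParams}}.
#' @param behavior \code{\link{behaviorParams}}.
#' @param analysis \code{\link{analysisParams}}.
#' @param spatial \code{\link{spatialParams}}.
#' @param seed global seed; stage seeds derive from it.
#' @param io list of optional paths: \code{movie} (input TIFF; when absent
#'   the pipeline simulates), \code{eyelid}, \code{events}.
#' @param writeIntermediates write every intermediate artifact to the
#'   output directory.
#' @return A validated list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(sim = simParams(), registration = registrationParams(),
                           detection = detectionParams(), merge = mergeParams(),
                           behavior = behaviorParams(),
                           analysis = analysisParams(),
                           spatial = spatialParams(), seed = 1, io = list(),
                           writeIntermediates = TRUE) {
  stopIfNot(is(sim, "SimParams"), "'sim' must be a SimParams object")
  for (nm in c("registration", "detection", "merge", "behavior", "analysis",
               "spatial")) {
    blk <- get(nm)
    cls <- paste0(toupper(substring(nm, 1, 1)), substring(nm, 2), "Params")
    stopIfNot(inherits(blk, cls), paste0("'", nm, "' must come from ", nm,
                                         "Params()"))
  }
  unknown <- setdiff(names(io), c("movie", "eyelid", "events"))
  stopIfNot(length(unknown) == 0,
            paste("unknown io keys:", paste(unknown, collapse = ", ")))
  structure(list(sim = sim, registration = registration,
                 detection = detection, merge = merge, behavior = behavior,
                 analysis = analysis, spatial = spatial, seed = seed,
                 io = io, writeIntermediates = isTRUE(writeIntermediates)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar overrides are applied on top of the package defaults; unknown
#' blocks or keys are rejected. The \code{sim} block maps onto
#' \code{\link{simParams}} arguments, and likewise for the other blocks.
#'
#' @param path a .yaml/.yml or .json file.
#' @return A \code{\link{pipelineConfig}} list.
#' @export
readPipelineConfig <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("sim", "registration", "detection", "merge", "behavior",
             "analysis", "spatial", "seed", "io", "writeIntermediates")
  unknown <- setdiff(names(raw), known)
  stopIfNot(length(unknown) == 0,
            paste("unknown config blocks:", paste(unknown, collapse = ", ")))
  ctor <- list(sim = simParams, registration = registrationParams,
               detection = detectionParams, merge = mergeParams,
               behavior = behaviorParams, analysis = analysisParams,
               spatial = spatialParams)
  args <- list()
  for (nm in names(ctor)) {
    blk <- raw[[nm]]
    if (is.null(blk)) blk <- list()
    bad <- setdiff(names(blk), names(formals(ctor[[nm]])))
    stopIfNot(length(bad) == 0,
              paste0("unknown keys in '", nm, "': ",
                     paste(bad, collapse = ", ")))
    args[[nm]] <- do.call(ctor[[nm]], blk)
  }
  args$seed <- if (is.null(raw$seed)) 1 else raw$seed
  args$io <- if (is.null(raw$io)) list() else raw$io
  if (!is.null(raw$writeIntermediates))
    args$writeIntermediates <- raw$writeIntermediates
  do.call(pipelineConfig, args)
}

stageMsg <- function(log, stage, ...) {
  if (log) message(sprintf("[widecal:%s] %s", stage, sprintf(...)))
}

#' Run the full pipeline
#'
#' simulate (or load) -> enhance + motion-correct -> pixel stats + 8-bit
#' reduction -> detect single-frame ROIs -> merge into multi-frame ROIs and
#' filter overlaps -> extract and normalize traces, SNR, photobleaching ->
#' score trials from the eyelid trace -> task-modulation and latency
#' statistics -> spatial statistics. Writes intermediates and a manifest
#' JSON with the configuration hash, seed, package version and per-stage
#' summary numbers; rerunning with the same config and seed reproduces the
#' manifest bit-exactly.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir output directory (created if needed).
#' @param log emit progress messages.
#' @return the manifest, invisibly; all artifacts are files under
#'   \code{outDir}.
#' @export
runPipeline <- function(config, outDir = tempfile("widecal"), log = TRUE) {
  stopIfNot(inherits(config, "PipelineConfig"),
            "'config' must come from pipelineConfig()")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  wInt <- config$writeIntermediates
  runStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  manifest <- list(package = "widecal",
                   version = as.character(utils::packageVersion("widecal")),
                   seed = config$seed, configHash = configHash(config),
                   stages = list())

  # --- stage: input ----------------------------------------------------------
  simulate <- is.null(config$io$movie)
  gt <- NULL
  runStage("input", {
    if (simulate) {
      stageMsg(log, "input", "simulating movie (%g x %g x %g)",
               config$sim@frameHeight, config$sim@frameWidth,
               config$sim@nFrames)
      gt <- makeGroundTruth(config$sim)
      movie <- renderMovie(gt, config$sim)
      eyelid <- renderEyelid(gt, config$sim)
      schedule <- gt@schedule
      if (nrow(schedule))
        schedule$outcome <- "unscored"   # scored from the eyelid trace below
    } else {
      movie <- readTiffSequence(config$io$movie,
                                frameRate = config$sim@frameRate,
                                pixelPitch = config$sim@pixelPitch)
      eyelid <- if (!is.null(config$io$eyelid)) readEyelid(config$io$eyelid)
                else NULL
      schedule <- if (!is.null(config$io$events)) readEvents(config$io$events)
                  else NULL
    }
    if (wInt && simulate) {
      writeTiffSequence(movie, file.path(outDir, "movie.tif"))
      writeEyelid(eyelid, movie@frameRate, file.path(outDir, "eyelid.csv"))
      writeEvents(schedule, file.path(outDir, "events.csv"))
    }
    movie <- movie; eyelid <- eyelid; schedule <- schedule
  })
  manifest$stages$input <- list(
    nFrames = nFrames(movie), frameDim = frameDim(movie),
    fovMm = as.numeric(fieldOfView(frameDim(movie), movie@pixelPitch)),
    simulated = simulate)

  # --- stage: preprocess -----------------------------------------------------
  corrected <- NULL; disp <- NULL
  runStage("preprocess", {
    stageMsg(log, "preprocess", "motion correction (%d frames)",
             nFrames(movie))
    res <- correctSequence(movie, config$registration, seed = config$seed)
    corrected <- res$video
    disp <- res$displacement
    if (wInt)
      utils::write.csv(data.frame(frame = disp$frame, dx_px = disp$dx,
                                  dy_px = disp$dy, mag_um = disp$magnitudeUm,
                                  peak_corr = disp$peakCorr),
                       file.path(outDir, "shifts.csv"), row.names = FALSE)
  })
  ds <- summarizeDisplacement(disp)
  manifest$stages$preprocess <- list(meanDisplacementUm = ds$meanUm,
                                     sdDisplacementUm = ds$sdUm)
  rm(movie)

  # --- stage: stats + reduction ---------------------------------------------
  stats <- NULL
  runStage("stats", {
    stageMsg(log, "stats", "per-pixel statistics")
    stats <- computePixelStats(corrected)
    if (wInt) {
      reduced <- reduceBitDepth(corrected, stats)
      writeTiffSequence(reduced, file.path(outDir, "reduced8bit.tif"),
                        bits = 8L)
    }
  })
  manifest$stages$stats <- list(
    bleachPercent = photobleachingPercent(corrected))

  # --- stage: detect ---------------------------------------------------------
  sfrois <- NULL
  runStage("detect", {
    stageMsg(log, "detect", "single-frame ROI detection")
    sfrois <- detectRois(corrected, stats, config$detection)
  })
  manifest$stages$detect <- list(nSingleFrameRois = nrow(sfrois))

  # --- stage: merge ----------------------------------------------------------
  rois <- NULL
  runStage("merge", {
    stageMsg(log, "merge", "clustering %d detections", nrow(sfrois))
    clustered <- clusterRois(sfrois, frameDim(corrected), config$merge,
                             pixelPitch = corrected@pixelPitch)
    rois <- filterSeparated(clustered, config$merge)
    if (wInt)
      writeRois(rois, file.path(outDir, "rois.json"),
                labelTiff = file.path(outDir, "rois.tif"))
  })
  manifest$stages$merge <- list(nRois = length(rois))

  # --- stage: traces ---------------------------------------------------------
  traces <- NULL; quality <- NULL
  runStage("traces", {
    stageMsg(log, "traces", "extracting %d traces", length(rois))
    traces <- normalizeTraces(extractTraces(corrected, rois))
    quality <- computeSnr(corrected, rois, traces, stats)
    if (wInt) {
      writeTraces(traces, file.path(outDir, "traces.csv"))
      jsonlite::write_json(list(snr = quality$snr,
                                noiseSigma = quality$noiseSigma),
                           file.path(outDir, "quality.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  })
  manifest$stages$traces <- list(snrMean = quality$meanSnr,
                                 snrSem = quality$semSnr,
                                 noiseSigma = quality$noiseSigma)

  # --- stage: behavior -------------------------------------------------------
  runStage("behavior", {
    if (!is.null(eyelid) && !is.null(schedule) && nrow(schedule) > 0) {
      schedule <- classifyTrials(eyelid, schedule, config$behavior,
                                  corrected@frameRate)
      if (wInt) writeEvents(schedule, file.path(outDir, "events_scored.csv"))
    }
  })
  manifest$stages$behavior <-
    if (!is.null(schedule) && nrow(schedule) > 0 &&
        any(schedule$outcome != "unscored"))
      list(nTrials = nrow(schedule),
           nCorrect = sum(schedule$outcome == "correct"),
           performancePercent = performancePercent(schedule))
    else list(nTrials = 0L)

  # --- stage: analyze --------------------------------------------------------
  modulation <- NULL
  runStage("analyze", {
    if (!is.null(schedule) && sum(schedule$outcome == "correct") >= 2 &&
        length(rois) > 0) {
      modulation <- analyzeTaskModulation(traces, schedule, config$analysis)
      if (wInt) {
        utils::write.csv(modulation, file.path(outDir, "modulation.csv"),
                         row.names = FALSE)
      }
    }
  })
  manifest$stages$analyze <- if (!is.null(modulation)) {
    summ <- summarizePopulation(modulation$label, config$analysis)
    list(nRois = nrow(modulation),
         nPositive = summ$count[summ$label == "positive"],
         pctPositive = summ$percent[summ$label == "positive"],
         nNegative = summ$count[summ$label == "negative"],
         pctNegative = summ$percent[summ$label == "negative"])
  } else list(nRois = 0L)

  # --- stage: spatial --------------------------------------------------------
  spatialRes <- NULL
  runStage("spatial", {
    if (!is.null(modulation) && length(rois) >= 4) {
      pts <- roiCentroids(rois, "um")
      pos <- which(modulation$label == "positive")
      rt <- if (length(pos) >= 2)
        resamplingTest(pts, pos, config$spatial) else NULL
      adj <- adjacencyCounts(pts, modulation$label, config$spatial)
      mw <- if (length(pos) >= 1 && length(pos) < nrow(pts))
        rankSumTest(adj$perRoi[pos, "positive"],
                    adj$perRoi[-pos, "positive"]) else NULL
      spatialRes <- list(resampling = rt, adjacency = adj, rankSum = mw)
      if (wInt)
        jsonlite::write_json(list(
          resampling = rt[c("observedMedianUm", "pValue", "nullMeanUm",
                            "nullSdUm", "tail")],
          adjacencyMean = as.data.frame(adj$mean),
          adjacencySd = as.data.frame(adj$sd),
          rankSum = mw), file.path(outDir, "spatial.json"),
          auto_unbox = TRUE, digits = NA)
    }
  })
  manifest$stages$spatial <- if (!is.null(spatialRes)) list(
    medianDistanceUm = spatialRes$resampling$observedMedianUm,
    resamplingP = spatialRes$resampling$pValue,
    nullMeanUm = spatialRes$resampling$nullMeanUm,
    rankSumZ = if (!is.null(spatialRes$rankSum)) spatialRes$rankSum$z,
    rankSumP = if (!is.null(spatialRes$rankSum)) spatialRes$rankSum$pValue)
  else list()

  # --- recovery scoring against ground truth ---------------------------------
  if (!is.null(gt) && length(rois) > 0 && nrow(gt@cellCenters) > 0) {
    sc <- scoreRecovery(rois, gt)
    manifest$stages$recovery <- sc
  }

  manifest$results <- list(rois = length(rois))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# md5 of the canonical JSON serialization of the config
configHash <- function(config) {
  ser <- jsonlite::serializeJSON(config)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(ser), tf)
  unname(tools::md5sum(tf))
}

#' Score detected ROIs against planted cells
#'
#' A detected ROI matches a planted cell when their centroids are within
#' one soma radius; matching is greedy by distance, one-to-one. Recall is
#' matched cells / planted cells; precision is matched ROIs / detected
#' ROIs.
#'
#' @param rois a \linkS4class{RoiSet}.
#' @param gt a \linkS4class{GroundTruth}.
#' @return list: recall, precision, nMatched, nRois, nCells.
#' @export
scoreRecovery <- function(rois, gt) {
  nC <- nrow(gt@cellCenters)
  nR <- length(rois)
  if (nC == 0 || nR == 0)
    return(list(recall = 0, precision = 0, nMatched = 0L, nRois = nR,
                nCells = nC))
  tol <- gt@params@somaRadius
  cc <- roiCentroids(rois, "px")
  D <- sqrt(outer(cc[, 1], gt@cellCenters[, 1], `-`)^2 +
            outer(cc[, 2], gt@cellCenters[, 2], `-`)^2)
  matched <- 0L
  usedR <- logical(nR); usedC <- logical(nC)
  repeat {
    D2 <- D
    D2[usedR, ] <- Inf
    D2[, usedC] <- Inf
    k <- which.min(D2)
    if (!length(k) || !is.finite(D2[k]) || D2[k] > tol) break
    i <- (k - 1) %% nR + 1
    j <- (k - 1) %/% nR + 1
    usedR[i] <- TRUE; usedC[j] <- TRUE
    matched <- matched + 1L
  }
  list(recall = matched / nC, precision = matched / nR,
       nMatched = matched, nRois = nR, nCells = nC)
}
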