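## End-to-end accelerated demonstration: fixture -> forward model ->
## baseline stream -> SSP + noise covariance + imaging kernel -> feedback
## runs streamed through a live buffer -> online alpha-power series ->
## offline recompute -> comparison + head-movement sweep + delay report.

#' Merged run configuration
#'
#' Bundles the simulation config, the paradigm schedule and the pipeline
#' parameters, all defaulting to the emulated study's conditions: 1 kHz
#' sampling, 500-ms updates with a 1000-point FFT (1-Hz bins), 8-13 Hz
#' band, 29-sample streaming chunks, 20-s paradigm segments, a 10-s
#' baseline run plus 3 x 130-s feedback runs, snr 3, depth exponent 0.5,
#' and 2 SSP components.
#'
#' @param seed master seed; every random element derives from it.
#' @param segmentMs real-time update period, ms.
#' @param nFft FFT length (zero-padded segments).
#' @param snr,gamma,sspK inverse-model parameters.
#' @param sim a \code{\link{simulationConfig}}.
#' @param schedule a \code{\link{paradigmSchedule}}.
#' @return a \code{RunConfig} list.
#' @export
runConfig <- function(seed = 1, segmentMs = 500, nFft = 1000,
                      snr = 3, gamma = 0.5, sspK = 2,
                      sim = simulationConfig(seed = seed),
                      schedule = paradigmSchedule()) {
  structure(list(seed = as.integer(seed), segmentMs = segmentMs, nFft = nFft,
                 snr = snr, gamma = gamma, sspK = as.integer(sspK),
                 sim = sim, schedule = schedule),
            class = "RunConfig")
}

#' Read a run configuration from a JSON file
#'
#' The structured-text configuration consumed by the CLI: a JSON object
#' whose optional top-level fields are \code{seed}, \code{segmentMs},
#' \code{nFft}, \code{snr}, \code{gamma}, \code{sspK}, plus \code{sim}
#' (arguments of \code{\link{simulationConfig}}) and \code{schedule}
#' (arguments of \code{\link{paradigmSchedule}}). Omitted fields take the
#' package defaults; the top-level seed propagates to the simulation config
#' unless the latter sets its own.
#'
#' @param path JSON file.
#' @return a \code{RunConfig} list.
#' @export
readRunConfig <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  seed <- j$seed %||% 1
  simArgs <- as.list(j$sim %||% list())
  if (is.null(simArgs$seed)) simArgs$seed <- seed
  schedArgs <- as.list(j$schedule %||% list())
  args <- j[setdiff(names(j), c("sim", "schedule"))]
  do.call(runConfig, c(args,
                       list(sim = do.call(simulationConfig, simArgs),
                            schedule = do.call(paradigmSchedule, schedArgs))))
}

## short config hash for output provenance (stable rolling hash, not crypto)
configHash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

## per-segment paradigm state labels for one run
segmentStates <- function(run, segmentSamples, samplingRate) {
  stateVec <- runStateVector(run, samplingRate)
  nSeg <- length(stateVec) %/% segmentSamples
  vapply(seq_len(nSeg), function(k)
    stateVec[(k - 1) * segmentSamples + segmentSamples %/% 2], character(1))
}

## factored synthesis of one run's sensor stream: (G M) L instead of
## G (M L), algebraically identical, never materializing the 750 x n
## source matrix
demoRunStream <- function(fixture, gain, schedule, config, run) {
  stateVec <- simRunState(schedule, config, run)
  M <- makeLoadings(fixture$sources, config)
  L <- makeLatents(stateVec, fixture$sources, config,
                   seed = config$seed + 1000L * run)
  GM <- values(gain) %*% M
  cues <- if (run == 0) integer(0)
          else runCueSamples(schedule$runs[[run]], config$samplingRate)
  addSensorLayers(GM %*% L, fixture$sensors, config, cues,
                  seed = config$seed + 7000L * (run + 1L))
}

#' Run the full accelerated end-to-end demonstration
#'
#' Executes the complete system on synthetic data: builds the geometry
#' fixture and forward model, streams the baseline run through a live
#' buffer, estimates the SSP projector and noise covariance from it,
#' precomputes the 750 x 306 imaging kernel, streams each feedback run
#' through the buffer in 29-sample chunks while recording it, runs the
#' 500-ms real-time loop (online arm), recomputes the series offline from
#' the recordings with shared denoising (collapse check), sweeps simulated
#' head displacements, and measures the chunked data-access delay
#' distribution. Everything is deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{runConfig}}.
#' @param outDir output directory (created); recordings, series tables,
#'   comparison tables, the delay report and the config provenance are
#'   written there, each file named with the seed and config hash.
#' @param sweep logical: run the head-displacement sweep (default TRUE).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with \code{fixture}, \code{kernel}, \code{ssp},
#'   \code{noise}, \code{onlineSeries}, \code{offlineSeries},
#'   \code{collapseRmsPercent}, \code{sweep}, \code{delay},
#'   \code{recordings} and \code{outDir}.
#' @export
runDemo <- function(config = runConfig(), outDir = tempfile("megstream-demo-"),
                    sweep = TRUE, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  tag <- sprintf("seed%d_%s", config$seed, configHash(config))
  sim <- config$sim
  schedule <- config$schedule
  fs <- sim$samplingRate
  segmentSamples <- as.integer(round(config$segmentMs / 1000 * fs))
  stageName <- "fixture"
  result <- tryCatch({
    say("[%s] building fixture and forward model", tag)
    fixture <- makeFixture(config$seed)
    spheres <- fitSpheres(fixture$scalp, fixture$sensors)
    gain <- computeGain(fixture$sources, fixture$sensors, spheres)
    nMeg <- nChannels(fixture$sensors)
    allLabels <- c(channelLabels(fixture$sensors),
                   fixture$sensors@triggerLabels)

    stageName <- "baseline"
    say("[%s] streaming baseline run", tag)
    header <- bufferHeader(length(allLabels), fs, allLabels,
                           dataType = "float32")
    buffer <- megBuffer()
    putHeader(buffer, header)
    baselineStream <- demoRunStream(fixture, gain, schedule, sim, 0)
    baselinePath <- file.path(outDir, sprintf("baseline_%s.rec", tag))
    sink0 <- recordingSink(baselinePath, header)
    streamToBuffer(buffer, baselineStream, sim$chunkSamples,
                   samplingRate = fs, recordTo = sink0)
    closeRecording(sink0)

    stageName <- "inverse"
    say("[%s] estimating SSP, noise covariance and imaging kernel", tag)
    baseMeg <- getData(buffer, 0, nSamplesWritten(buffer))@values[
      seq_len(nMeg), , drop = FALSE]
    rownames(baseMeg) <- channelLabels(fixture$sensors)
    ssp <- computeSsp(baseMeg, config$sspK)
    noise <- estimateNoiseCovariance(applySsp(ssp, baseMeg), fs)
    kernel <- computeWmneKernel(gain, noise, ssp, snr = config$snr,
                                gamma = config$gamma)
    rm(baselineStream, baseMeg)

    stageName <- "feedback-runs"
    recordings <- character(0)
    onlineSeries <- list()
    for (r in seq_along(schedule$runs)) {
      say("[%s] run %d: streaming and online analysis", tag, r)
      stream <- demoRunStream(fixture, gain, schedule, sim, r)
      putHeader(buffer, header)              # new run, reset counters
      path <- file.path(outDir, sprintf("run%d_%s.rec", r, tag))
      sinkR <- recordingSink(path, header)
      streamToBuffer(buffer, stream, sim$chunkSamples, samplingRate = fs,
                     recordTo = sinkR)
      closeRecording(sinkR)
      rm(stream)
      states <- segmentStates(schedule$runs[[r]], segmentSamples, fs)
      nSeg <- round(schedule$runs[[r]]$duration * fs) %/% segmentSamples
      onlineSeries[[r]] <- runRealtimeLoop(
        buffer, kernel, nMegChannels = nMeg, startSample = 0,
        nSegments = nSeg, segmentSamples = segmentSamples,
        nFft = config$nFft, baselineSegments = 40L, samplingRate = fs,
        runId = sprintf("online-run%d", r), states = states,
        logFile = file.path(outDir, sprintf("online_log_%s.tsv", tag)))
      recordings <- c(recordings, path)
    }

    stageName <- "offline-collapse"
    say("[%s] offline recompute (shared head position and denoising)", tag)
    identityPos <- lapply(seq_along(recordings), function(r)
      headPosition(sprintf("run%d", r)))
    offlineSeries <- recomputeOffline(recordings, identityPos, fixture,
                                      ssp = ssp, noise = noise,
                                      snr = config$snr, gamma = config$gamma,
                                      segmentSamples = segmentSamples,
                                      nFft = config$nFft)
    collapse <- vapply(seq_along(recordings), function(r)
      rmsPercentDifference(seriesZ(onlineSeries[[r]]),
                           seriesZ(offlineSeries[[r]])), numeric(1))

    stageName <- "head-movement-sweep"
    sweepTab <- NULL
    if (sweep) {
      say("[%s] head-displacement sweep", tag)
      sweepTab <- headMovementSweep(onlineSeries, recordings, fixture,
                                    ssp, noise,
                                    segmentSamples = segmentSamples,
                                    nFft = config$nFft)
    }

    stageName <- "delay"
    say("[%s] loopback delay measurement", tag)
    delayDist <- runLoopback(delayConfig(chunkSamples = sim$chunkSamples,
                                         samplingRate = fs))
    delayReport <- compareDelayToReference(delayDist)

    stageName <- "outputs"
    allRecords <- do.call(rbind, lapply(seq_along(onlineSeries), function(r)
      cbind(run = r, records(onlineSeries[[r]]))))
    utils::write.csv(allRecords,
                     file.path(outDir, sprintf("series_online_%s.csv", tag)),
                     row.names = FALSE)
    allOffline <- do.call(rbind, lapply(seq_along(offlineSeries), function(r)
      cbind(run = r, records(offlineSeries[[r]]))))
    utils::write.csv(allOffline,
                     file.path(outDir, sprintf("series_offline_%s.csv", tag)),
                     row.names = FALSE)
    if (!is.null(sweepTab))
      utils::write.csv(sweepTab,
                       file.path(outDir, sprintf("sweep_%s.csv", tag)),
                       row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, configHash = configHash(config),
           segmentMs = config$segmentMs, nFft = config$nFft,
           snr = config$snr, gamma = config$gamma, sspK = config$sspK,
           sim = unclass(sim),
           baselineDuration = schedule$baselineDuration,
           nRuns = length(schedule$runs),
           kernelRows = nrow(values(kernel)),
           kernelCols = ncol(values(kernel)),
           kernelGainFingerprint = kernel@gainFingerprint,
           collapseRmsPercent = collapse,
           delay = delayReport$measured),
      file.path(outDir, sprintf("provenance_%s.json", tag)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(fixture = fixture, spheres = spheres, gain = gain, kernel = kernel,
         ssp = ssp, noise = noise, onlineSeries = onlineSeries,
         offlineSeries = offlineSeries, collapseRmsPercent = collapse,
         sweep = sweepTab, delay = delayReport, recordings = recordings,
         baselineRecording = baselinePath, outDir = outDir, tag = tag)
  }, error = function(e) {
    stop(sprintf("demo failed at stage '%s' (partial outputs retained in %s): %s",
                 stageName, outDir, conditionMessage(e)), call. = FALSE)
  })
  say("[%s] done: %s", tag, outDir)
  invisible(result)
}
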