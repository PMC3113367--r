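## Acquisition-chain simulator: alpha-band source activity modulated by an
## eyes-open/eyes-closed paradigm, projected to the 306-channel array through
## the forward gain, plus low-rank environmental interference and white
## sensor noise, streamed to the buffer in DSP-like chunks.

DSP_MIN_CHUNK <- 28L   # acquisition DSP packet lower bound, samples

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic acquisition chain. Defaults are
#' the study conditions of the emulated experiment (1 kHz sampling, 8-13 Hz
#' alpha band, eyes-closed/eyes-open source amplitude ratio 3, 29-sample
#' streaming chunks) with source/noise magnitudes calibrated to typical
#' physiological and instrumental scales: per-dipole eyes-closed alpha
#' moments of ~1.5 nA m (hundreds of semi-coherent patch dipoles then
#' produce posterior sensor-level alpha of a few hundred fT, the textbook
#' scale of the eyes-closed rhythm), magnetometer noise of ~70 fT RMS and
#' gradiometer noise of ~5.6 pT/m RMS per sample at 1 kHz (white densities
#' of ~3 fT/sqrt(Hz) and ~2.5 fT/cm/sqrt(Hz)), and rank-2 environmental
#' interference of a few pT.
#'
#' @param samplingRate Hz.
#' @param chunkSamples streaming chunk size; must be >= 28, the acquisition
#'   DSP packet lower bound.
#' @param band alpha band edges in Hz.
#' @param amplitudeRatio eyes-closed / eyes-open PO source amplitude ratio
#'   (>= 1; 1 means no modulation).
#' @param amplitudeClosed eyes-closed per-dipole RMS moment, A m.
#' @param amplitudePfc state-independent prefrontal per-dipole RMS moment, A m.
#' @param latentsPerRoi number of independent alpha processes per ROI
#'   (alpha is spatially coherent; each dipole mixes its ROI's latents).
#' @param magNoiseSd,gradNoiseSd white sensor noise SD (T, T/m).
#' @param interferenceRank number of interference spatial patterns.
#' @param interferenceMagSd,interferenceGradSd per-channel scale of the
#'   interference patterns (T, T/m).
#' @param seed integer seed driving every random element.
#' @return a validated \code{SimulationConfig} list.
#' @export
simulationConfig <- function(samplingRate = 1000, chunkSamples = 29,
                             band = c(8, 13), amplitudeRatio = 3,
                             amplitudeClosed = 1.5e-9, amplitudePfc = 5e-10,
                             latentsPerRoi = 5,
                             magNoiseSd = 7e-14, gradNoiseSd = 5.6e-12,
                             interferenceRank = 2,
                             interferenceMagSd = 2e-12,
                             interferenceGradSd = 2e-11,
                             seed = 1) {
  if (chunkSamples < DSP_MIN_CHUNK)
    stopConfig(sprintf(
      "chunkSamples = %d is below the %d-sample DSP lower bound",
      chunkSamples, DSP_MIN_CHUNK))
  if (amplitudeRatio < 1)
    stopConfig("amplitudeRatio must be >= 1 (eyes-closed at least as strong)")
  if (band[1] <= 0 || band[2] <= band[1] || band[2] > samplingRate / 2)
    stopConfig("band must satisfy 0 < low < high <= Nyquist")
  structure(list(samplingRate = samplingRate,
                 chunkSamples = as.integer(chunkSamples), band = band,
                 amplitudeRatio = amplitudeRatio,
                 amplitudeClosed = amplitudeClosed,
                 amplitudePfc = amplitudePfc,
                 latentsPerRoi = as.integer(latentsPerRoi),
                 magNoiseSd = magNoiseSd, gradNoiseSd = gradNoiseSd,
                 interferenceRank = as.integer(interferenceRank),
                 interferenceMagSd = interferenceMagSd,
                 interferenceGradSd = interferenceGradSd,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Paradigm schedule
#'
#' The eyes-open/eyes-closed alternation paradigm: a short eyes-open
#' baseline run, then feedback runs tiled by alternating fixed-length
#' segments. Each run starts with a 20-s eyes-open reference window (its
#' first segment), used to freeze the Z-score baseline; the final segment is
#' truncated at the run end when the run duration is not a segment multiple.
#'
#' @param baselineDuration baseline-run length, s (default 10).
#' @param nRuns number of feedback runs (default 3).
#' @param runDuration feedback-run length, s (default 130).
#' @param segmentLength paradigm segment length, s (default 20).
#' @param startingState state of each run's first segment
#'   (default "open": the eyes-open reference window).
#' @param feedbackEnabled logical, one per run (recycled).
#' @return a validated \code{ParadigmSchedule} list; element \code{runs} is a
#'   list of per-run descriptors with precomputed segment state tables.
#' @export
paradigmSchedule <- function(baselineDuration = 10, nRuns = 3,
                             runDuration = 130, segmentLength = 20,
                             startingState = "open",
                             feedbackEnabled = TRUE) {
  if (baselineDuration <= 0 || runDuration <= 0 || segmentLength <= 0)
    stopConfig("durations must be positive")
  startingState <- match.arg(startingState, c("open", "closed"))
  feedbackEnabled <- rep_len(feedbackEnabled, nRuns)
  runs <- lapply(seq_len(nRuns), function(r) {
    starts <- seq(0, runDuration - 1e-9, by = segmentLength)
    ends <- pmin(starts + segmentLength, runDuration)
    states <- rep(c(startingState, setdiff(c("open", "closed"), startingState)),
                  length.out = length(starts))
    list(duration = runDuration, segmentLength = segmentLength,
         feedbackEnabled = feedbackEnabled[r],
         segments = data.frame(start = starts, end = ends, state = states,
                               stringsAsFactors = FALSE))
  })
  structure(list(baselineDuration = baselineDuration, runs = runs),
            class = "ParadigmSchedule")
}

## per-sample paradigm state for one run ("open"/"closed" character vector)
runStateVector <- function(run, samplingRate) {
  n <- round(run$duration * samplingRate)
  state <- character(n)
  for (i in seq_len(nrow(run$segments))) {
    a <- floor(run$segments$start[i] * samplingRate) + 1L
    b <- floor(run$segments$end[i] * samplingRate - 1e-9) + 1L
    state[a:min(b, n)] <- run$segments$state[i]
  }
  state
}

## cue sample indices (0-based) at segment transitions within a run
runCueSamples <- function(run, samplingRate) {
  round(run$segments$start[-1] * samplingRate)
}

## zero-phase brick-wall band-pass via FFT; returns unit-RMS series
bandLimitedNoise <- function(n, samplingRate, band) {
  x <- stats::rnorm(n)
  f <- (seq_len(n) - 1) * samplingRate / n
  f <- pmin(f, samplingRate - f)               # two-sided frequency axis
  X <- stats::fft(x)
  X[f < band[1] | f > band[2]] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / sqrt(mean(y^2))
}

## slow (< maxFreq Hz) unit-RMS drift for interference time courses
slowDrift <- function(n, samplingRate, maxFreq = 2) {
  x <- cumsum(stats::rnorm(n))
  f <- (seq_len(n) - 1) * samplingRate / n
  f <- pmin(f, samplingRate - f)
  X <- stats::fft(x)
  X[f > maxFreq] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y <- y - mean(y)
  y / sqrt(mean(y^2))
}

## raised-cosine smoothing of a per-sample amplitude target (rampMs ramp)
smoothEnvelope <- function(target, samplingRate, rampMs = 200) {
  k <- max(1L, round(rampMs / 1000 * samplingRate))
  w <- 0.5 * (1 - cos(2 * pi * seq_len(k) / (k + 1)))
  w <- w / sum(w)
  as.vector(stats::filter(c(rep(target[1], k), target, rep(target[length(target)], k)),
                          w, sides = 2))[(k + 1):(k + length(target))]
}

## per-ROI latent envelope for one run (or the baseline run)
roiEnvelope <- function(stateVec, roi, config) {
  if (roi == "PFC") return(rep(config$amplitudePfc, length(stateVec)))
  target <- ifelse(stateVec == "closed",
                   config$amplitudeClosed,
                   config$amplitudeClosed / config$amplitudeRatio)
  smoothEnvelope(target, config$samplingRate)
}

## dipole-to-latent loading matrix, deterministic from config$seed
makeLoadings <- function(sources, config) {
  withSeed(config$seed + 211L, {
    roi <- as.character(sources@roi)
    K <- config$latentsPerRoi
    rois <- levels(sources@roi)
    M <- matrix(0, nDipoles(sources), length(rois) * K)
    for (j in seq_along(rois)) {
      rows <- which(roi == rois[j])
      w <- abs(matrix(stats::rnorm(length(rows) * K, 1, 0.3),
                      length(rows), K))
      w <- w / sqrt(rowSums(w^2))              # unit per-dipole RMS mix
      M[rows, (j - 1) * K + seq_len(K)] <- w
    }
    dimnames(M) <- list(NULL, paste(rep(rois, each = K), seq_len(K), sep = "."))
    M
  })
}

## latent matrix (nLatents x n) for a given per-sample state vector
makeLatents <- function(stateVec, sources, config, seed) {
  withSeed(seed, {
    K <- config$latentsPerRoi
    rois <- levels(sources@roi)
    n <- length(stateVec)
    L <- matrix(0, length(rois) * K, n)
    for (j in seq_along(rois)) {
      env <- roiEnvelope(stateVec, rois[j], config)
      for (k in seq_len(K)) {
        L[(j - 1) * K + k, ] <-
          env * bandLimitedNoise(n, config$samplingRate, config$band)
      }
    }
    L
  })
}

#' Simulate alpha-band source activity
#'
#' Generates the dipole moment time series for one run of the paradigm:
#' each parieto-occipital dipole mixes its ROI's band-limited (8-13 Hz)
#' latent alpha processes, whose envelope follows the eyes-open/eyes-closed
#' state (amplitude \code{amplitudeClosed} when closed, divided by
#' \code{amplitudeRatio} when open, with a 200-ms raised-cosine transition);
#' prefrontal dipoles carry weak state-independent alpha. Reproducible given
#' the config seed.
#'
#' @param schedule a \code{\link{paradigmSchedule}}.
#' @param config a \code{\link{simulationConfig}}.
#' @param sources the \linkS4class{SourceSpace}.
#' @param run which feedback run to simulate (1-based), or 0 for the
#'   baseline run.
#' @return matrix of dipole moments, nDipoles x nSamples (A m).
#' @export
simulateSourceActivity <- function(schedule, config, sources, run = 1) {
  if (config$amplitudeRatio < 1)
    stopConfig("amplitudeRatio must be >= 1")
  stateVec <- simRunState(schedule, config, run)
  M <- makeLoadings(sources, config)
  L <- makeLatents(stateVec, sources, config, seed = config$seed + 1000L * run)
  M %*% L
}

## per-sample state for run index (0 = baseline run, eyes open)
simRunState <- function(schedule, config, run) {
  if (run == 0)
    rep("open", round(schedule$baselineDuration * config$samplingRate))
  else
    runStateVector(schedule$runs[[run]], config$samplingRate)
}

## fixed interference spatial patterns, deterministic from config$seed
makeInterferencePatterns <- function(sensors, config) {
  withSeed(config$seed + 977L, {
    scale <- ifelse(sensors@channels$kind == "mag",
                    config$interferenceMagSd, config$interferenceGradSd)
    matrix(stats::rnorm(nChannels(sensors) * config$interferenceRank),
           nChannels(sensors)) * scale
  })
}

#' Synthesize the calibrated sensor stream
#'
#' Projects source activity to the MEG channels through the forward gain and
#' adds rank-limited environmental interference (fixed spatial patterns
#' times slow < 2 Hz drifts) and white sensor noise. Trigger channel rows
#' are appended: the first trigger channel carries the paradigm cue pulses
#' (value 2, held 100 ms), the remaining trigger channels are zero. The
#' result is quantized to float32-representable values, the precision the
#' stream has end-to-end (buffer wire format and recordings), so recordings
#' are lossless mirrors of the live stream.
#'
#' @param sourceActivity nDipoles x nSamples moment matrix (A m), e.g. from
#'   \code{\link{simulateSourceActivity}}.
#' @param gain the \linkS4class{GainMatrix} matching the source space.
#' @param sensors the \linkS4class{SensorArray}.
#' @param config a \code{\link{simulationConfig}}; set noise/interference
#'   scales to 0 for a noise-free projection.
#' @param cueSamples 0-based sample indices at which cue pulses start.
#' @param seed seed for the noise and interference draws (the config seed
#'   plus a run offset in the demo).
#' @return (nChannels + nTrigger) x nSamples matrix; MEG rows in physical
#'   units (T, T/m), trigger rows integer-valued.
#' @export
synthesizeSensorStream <- function(sourceActivity, gain, sensors, config,
                                   cueSamples = integer(0), seed = config$seed) {
  if (ncol(values(gain)) != nrow(sourceActivity))
    stopConfig("gain columns must match source rows")
  if (nrow(values(gain)) != nChannels(sensors))
    stopConfig("gain rows must match sensor channels")
  meg <- values(gain) %*% sourceActivity
  addSensorLayers(meg, sensors, config, cueSamples, seed)
}

## Add interference + sensor noise + trigger rows to a clean MEG projection
## and quantize; shared by synthesizeSensorStream and the factored demo path.
addSensorLayers <- function(meg, sensors, config, cueSamples, seed) {
  n <- ncol(meg)
  nCh <- nChannels(sensors)
  withSeed(seed + 3131L, {
    if (config$interferenceRank > 0 &&
        (config$interferenceMagSd > 0 || config$interferenceGradSd > 0)) {
      patterns <- makeInterferencePatterns(sensors, config)
      drifts <- t(vapply(seq_len(config$interferenceRank),
                         function(k) slowDrift(n, config$samplingRate),
                         numeric(n)))
      meg <- meg + patterns %*% drifts
    }
    if (config$magNoiseSd > 0 || config$gradNoiseSd > 0) {
      sd <- ifelse(sensors@channels$kind == "mag",
                   config$magNoiseSd, config$gradNoiseSd)
      meg <- meg + matrix(stats::rnorm(nCh * n), nCh, n) * sd
    }
  })
  trig <- matrix(0, length(sensors@triggerLabels), n)
  holdSamples <- round(0.1 * config$samplingRate)
  for (s in cueSamples) {
    idx <- (s + 1):min(s + holdSamples, n)
    trig[1, idx] <- 2
  }
  out <- rbind(meg, trig)
  rownames(out) <- c(channelLabels(sensors), sensors@triggerLabels)
  quantizeFloat32(out)
}

#' Round to float32-representable values
#'
#' @param x numeric vector or matrix.
#' @return \code{x} with every value rounded to the nearest single-precision
#'   float (the stream's end-to-end precision).
#' @export
quantizeFloat32 <- function(x) {
  q <- readBin(writeBin(as.numeric(x), raw(), size = 4L), double(),
               n = length(x), size = 4L)
  if (is.matrix(x)) {
    q <- matrix(q, nrow(x), ncol(x))
    dimnames(q) <- dimnames(x)
  }
  q
}

#' Convert between physical values and raw calibrated counts
#'
#' The acquisition chain stores per-channel calibration coefficients
#' (physical units per raw unit). \code{physicalToRaw} quantizes MEG rows to
#' integer raw counts; \code{rawToPhysical} applies the coefficients back.
#' Round-tripping recovers physical values within one quantization step
#' (half a coefficient).
#'
#' @param stream (nChannels + nTrigger) x nSamples matrix.
#' @param sensors the \linkS4class{SensorArray} carrying the coefficients.
#' @return matrix of the same shape.
#' @export
physicalToRaw <- function(stream, sensors) {
  nCh <- nChannels(sensors)
  coef <- sensors@channels$calibration
  out <- stream
  out[seq_len(nCh), ] <- round(stream[seq_len(nCh), , drop = FALSE] / coef)
  out
}

#' @rdname physicalToRaw
#' @export
rawToPhysical <- function(stream, sensors) {
  nCh <- nChannels(sensors)
  coef <- sensors@channels$calibration
  out <- stream
  out[seq_len(nCh), ] <- stream[seq_len(nCh), , drop = FALSE] * coef
  out
}

#' Stream a sensor matrix to a buffer in DSP-like chunks
#'
#' Writes \code{stream} to the buffer in chunks of exactly
#' \code{chunkSamples} columns (final partial chunk allowed). In
#' \code{"realtime"} pacing, chunk k is not written before wall-clock time
#' k * chunkSamples / samplingRate; \code{"accelerated"} pacing writes as
#' fast as possible and yields bit-identical buffer contents.
#'
#' @param buffer a \linkS4class{MegBuffer} whose header matches the stream.
#' @param stream channels x samples matrix.
#' @param chunkSamples chunk size, >= 28 (the DSP lower bound).
#' @param pacing \code{"accelerated"} or \code{"realtime"}.
#' @param samplingRate Hz (used for realtime pacing).
#' @param onChunk optional callback \code{function(totalSamples)} invoked
#'   after each chunk is committed (hook for in-process real-time clients).
#' @param recordTo optional recording sink from \code{\link{recordingSink}};
#'   every chunk is also appended there.
#' @return list with \code{chunksSent} and \code{samplesSent}.
#' @export
streamToBuffer <- function(buffer, stream, chunkSamples = 29,
                           pacing = c("accelerated", "realtime"),
                           samplingRate = 1000, onChunk = NULL,
                           recordTo = NULL) {
  pacing <- match.arg(pacing)
  if (chunkSamples < DSP_MIN_CHUNK)
    stopConfig(sprintf(
      "chunkSamples = %d is below the %d-sample DSP lower bound",
      chunkSamples, DSP_MIN_CHUNK))
  requireHeader(buffer)
  n <- ncol(stream)
  starts <- seq(1L, n, by = chunkSamples)
  t0 <- Sys.time()
  chunks <- 0L
  for (s in starts) {
    e <- min(s + chunkSamples - 1L, n)
    if (pacing == "realtime") {
      due <- t0 + (e / samplingRate)
      dt <- as.numeric(due - Sys.time(), units = "secs")
      if (dt > 0) Sys.sleep(dt)
    }
    chunk <- stream[, s:e, drop = FALSE]
    putData(buffer, chunk)
    if (!is.null(recordTo)) recordChunk(recordTo, chunk)
    chunks <- chunks + 1L
    if (!is.null(onChunk)) onChunk(nSamplesWritten(buffer))
  }
  list(chunksSent = chunks, samplesSent = n)
}
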