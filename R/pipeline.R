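## The real-time loop: every 500 ms pull the newest segment from the buffer,
## FFT it (rectangular window, zero-padded to 1000 bins for 1-Hz spacing),
## apply the precomputed imaging kernel to the Fourier coefficients, sum the
## coefficient magnitudes over the 8-13 Hz bins and the ROI sources, Z-score
## against the run's frozen 20-s baseline, and emit the inverse-power gauge.

#' Extract the most recent segment from a buffer
#'
#' Returns the latest \code{segmentSamples} columns. If fewer samples exist,
#' waits via \code{\link{waitForSamples}} up to \code{timeoutMs}; an
#' unsatisfied wait raises a "not yet available" error. In the scheduled
#' loop, consecutive calls advance by exactly one segment (non-overlapping
#' tiling).
#'
#' @param buffer a \linkS4class{MegBuffer}.
#' @param segmentSamples segment length in samples (500 at 1 kHz for the
#'   500-ms update).
#' @param timeoutMs how long to wait for enough samples (default 0).
#' @return a \linkS4class{SampleBlock} covering
#'   \code{[total - segmentSamples, total)}.
#' @export
extractLatestSegment <- function(buffer, segmentSamples, timeoutMs = 0) {
  total <- waitForSamples(buffer, segmentSamples, timeoutMs)
  if (total < segmentSamples)
    stopNotAvailable(sprintf(
      "only %d of the %d samples needed are available", total, segmentSamples))
  getData(buffer, total - segmentSamples, total)
}

#' One-sided FFT of a sensor segment
#'
#' Rectangular window, zero-padded to \code{nFft} points (default 1000 for a
#' 500-sample segment, giving 1-Hz bin spacing), one-sided spectrum of
#' \code{nFft/2 + 1} bins. Truncation is refused: \code{nFft} must be at
#' least the segment length.
#'
#' @param segment a \linkS4class{SampleBlock} or channels x samples matrix.
#' @param nFft FFT length (>= segment length).
#' @param samplingRate Hz (taken as 1000 when the segment is a bare matrix).
#' @return a \linkS4class{SegmentSpectrum}.
#' @examples
#' seg <- matrix(sin(2 * pi * 10 * (0:499) / 1000), 1, 500)
#' sp <- segmentFft(seg, 1000)
#' sp@frequencies[which.max(Mod(sp@coefficients[1, ]))]  # 10 Hz
#' @export
segmentFft <- function(segment, nFft = 1000, samplingRate = 1000) {
  if (is(segment, "SampleBlock")) {
    start <- segment@firstSampleIndex
    segment <- segment@values
  } else start <- 0
  nSamp <- ncol(segment)
  if (nFft < nSamp)
    stopConfig(sprintf("nFft = %d would truncate the %d-sample segment",
                       nFft, nSamp))
  padded <- cbind(segment, matrix(0, nrow(segment), nFft - nSamp))
  X <- t(stats::mvfft(t(padded)))              # channels x nFft
  nBins <- nFft %/% 2L + 1L
  new("SegmentSpectrum",
      coefficients = X[, seq_len(nBins), drop = FALSE],
      frequencies = (seq_len(nBins) - 1) * samplingRate / nFft,
      startIndex = start, samplingRate = samplingRate,
      segmentSamples = as.integer(nSamp))
}

#' ROI alpha power from an imaging kernel and a segment spectrum
#'
#' Applies the imaging kernel to the sensor Fourier coefficients and sums
#' the magnitudes of the source-level coefficients over the alpha bins
#' (frequencies in [8, 13] Hz inclusive: 6 bins at 1-Hz spacing) and over
#' every source of the requested ROI:
#' \eqn{\sum_{sources} \sum_{bins} |(K \cdot FFT(b))_{source,bin}|}.
#' By linearity of the FFT this equals FFT-ing the kernel-projected source
#' time series instead, but the kernel-times-coefficients order costs a
#' single small matrix product per update. The statistic is homogeneous of
#' degree 1 (magnitudes, not squared magnitudes, are summed).
#'
#' @param spectrum a \linkS4class{SegmentSpectrum}.
#' @param kernel an \linkS4class{ImagingKernel}.
#' @param roi ROI label ("PO" or "PFC" in the default fixture).
#' @param band band edges in Hz, inclusive (default c(8, 13)).
#' @return non-negative scalar raw power (summed coefficient magnitudes).
#' @export
roiAlphaPower <- function(spectrum, kernel, roi, band = c(8, 13)) {
  if (ncol(kernel@values) != nrow(spectrum@coefficients))
    stopConfig("kernel channel count does not match the spectrum")
  if (band[2] > max(spectrum@frequencies))
    stopConfig("band exceeds the Nyquist frequency of the spectrum")
  rows <- which(as.character(kernel@roi) == roi)
  if (length(rows) == 0L)
    stopConfig(sprintf("ROI '%s' is absent from the kernel", roi))
  bins <- which(spectrum@frequencies >= band[1] & spectrum@frequencies <= band[2])
  src <- kernel@values[rows, , drop = FALSE] %*%
    spectrum@coefficients[, bins, drop = FALSE]
  sum(Mod(src))
}

#' Freeze baseline statistics for Z-scoring
#'
#' Mean and SD over the baseline window's segment powers (the first 20 s of
#' a run: 40 segments at the 500-ms update). The statistics are frozen for
#' the remainder of the run. Degenerate baselines (SD = 0) are refused.
#'
#' @param powers numeric vector of baseline segment powers (length >= 2).
#' @return list with \code{mean}, \code{sd}, \code{n}.
#' @export
computeBaselineStats <- function(powers) {
  if (length(powers) < 2) stopConfig("need at least 2 baseline segments")
  s <- stats::sd(powers)
  if (s == 0) stopConfig("baseline power SD is zero; cannot Z-score")
  list(mean = mean(powers), sd = s, n = length(powers))
}

#' Inverse-power feedback gauge
#'
#' The visual gauge is indexed to the inverse of current ROI alpha power:
#' gauge = baseline mean / current power. It equals 1 at baseline level,
#' rises as alpha power falls, and the target is reached at
#' \code{gauge >= targetLevel} (default 2, i.e. half-baseline power).
#' A zero power is capped at \code{capValue} with a warning.
#'
#' @param rawPower current segment raw power (>= 0).
#' @param baselineMean frozen baseline mean power (> 0).
#' @param targetLevel gauge level counted as target reached.
#' @param capValue gauge value substituted for zero power.
#' @return list with \code{gauge} and logical \code{targetReached}.
#' @export
feedbackValue <- function(rawPower, baselineMean, targetLevel = 2,
                          capValue = 100) {
  if (baselineMean <= 0) stopConfig("baselineMean must be > 0")
  if (rawPower == 0) {
    warning("zero segment power; feedback gauge capped at ", capValue)
    gauge <- capValue
  } else {
    gauge <- baselineMean / rawPower
  }
  list(gauge = gauge, targetReached = gauge >= targetLevel)
}

#' Run the real-time analysis loop over one run
#'
#' Tiles the run into consecutive non-overlapping segments (500 ms by
#' default), and for each segment: waits for the samples, FFTs the MEG rows,
#' applies the imaging kernel to the Fourier coefficients, computes each
#' ROI's alpha power, Z-scores it against the run's frozen baseline window
#' (the first \code{baselineSegments} segments), and computes the feedback
#' gauge. Wall-clock processing time per segment is recorded. In accelerated
#' replay no segment is ever skipped; \code{logFile}, when given, receives
#' one delimited line per segment per ROI.
#'
#' @param buffer a \linkS4class{MegBuffer} holding (or receiving) the run.
#' @param kernel the precomputed \linkS4class{ImagingKernel}.
#' @param nMegChannels number of MEG rows at the top of the stream (kernel
#'   channels); trigger rows below are excluded from analysis.
#' @param startSample 0-based global sample at which the run starts.
#' @param nSegments number of segments to process (e.g. 260 for a 130-s run
#'   at 500 ms); \code{NULL} processes to the end of the buffered data.
#' @param segmentSamples samples per segment (default 500).
#' @param nFft FFT length (default 1000).
#' @param band alpha band in Hz.
#' @param baselineSegments segments in the frozen baseline window
#'   (default 40 = 20 s / 500 ms).
#' @param rois ROI labels to track.
#' @param samplingRate Hz.
#' @param timeoutMs per-segment wait timeout.
#' @param runId free-text run identifier.
#' @param states optional per-segment paradigm state labels (recorded in the
#'   output for analysis).
#' @param logFile optional path; one line per segment per ROI is appended.
#' @return an \linkS4class{AlphaPowerSeries}.
#' @export
runRealtimeLoop <- function(buffer, kernel, nMegChannels = ncol(kernel@values),
                            startSample = 0, nSegments = NULL,
                            segmentSamples = 500L, nFft = 1000L,
                            band = c(8, 13), baselineSegments = 40L,
                            rois = levels(kernel@roi), samplingRate = 1000,
                            timeoutMs = 0, runId = "run",
                            states = NULL, logFile = NULL) {
  if (is.null(nSegments)) {
    avail <- nSamplesWritten(buffer) - startSample
    nSegments <- avail %/% segmentSamples
  }
  if (nSegments < baselineSegments)
    stopConfig("run shorter than the baseline window")
  spectra <- vector("list", nSegments)
  procMs <- numeric(nSegments)
  for (k in seq_len(nSegments)) {
    a <- startSample + (k - 1) * segmentSamples
    b <- a + segmentSamples
    waitForSamples(buffer, b, timeoutMs)
    t0 <- proc.time()[["elapsed"]]
    blk <- getData(buffer, a, b)
    seg <- blk@values[seq_len(nMegChannels), , drop = FALSE]
    spectra[[k]] <- segmentFft(seg, nFft, samplingRate)
    spectra[[k]]@startIndex <- a
    procMs[k] <- (proc.time()[["elapsed"]] - t0) * 1000
  }
  powerSeriesFromSpectra(spectra, kernel, band = band,
                         baselineSegments = baselineSegments, rois = rois,
                         segmentSamples = segmentSamples,
                         samplingRate = samplingRate, runId = runId,
                         states = states, procMs = procMs, logFile = logFile)
}

## Assemble an AlphaPowerSeries from precomputed segment spectra. Shared by
## the live loop and the offline recompute (which reuses spectra across
## candidate head positions).
powerSeriesFromSpectra <- function(spectra, kernel, band = c(8, 13),
                                   baselineSegments = 40L,
                                   rois = levels(kernel@roi),
                                   segmentSamples = 500L, samplingRate = 1000,
                                   runId = "run", states = NULL,
                                   procMs = NULL, logFile = NULL) {
  nSegments <- length(spectra)
  if (is.null(procMs)) procMs <- rep(NA_real_, nSegments)
  if (is.null(states)) states <- rep(NA_character_, nSegments)
  recs <- list()
  baseline <- list()
  for (roi in rois) {
    t0 <- proc.time()[["elapsed"]]
    raw <- vapply(spectra, roiAlphaPower, numeric(1), kernel = kernel,
                  roi = roi, band = band)
    bl <- computeBaselineStats(raw[seq_len(baselineSegments)])
    z <- (raw - bl$mean) / bl$sd
    gauge <- vapply(raw, function(p)
      feedbackValue(p, bl$mean)$gauge, numeric(1))
    baseline[[roi]] <- bl
    recs[[roi]] <- data.frame(
      segment = seq_len(nSegments) - 1L,
      startIndex = vapply(spectra, function(s) s@startIndex, numeric(1)),
      roi = roi, raw = raw, z = z, gauge = gauge,
      state = states,
      procMs = procMs + (proc.time()[["elapsed"]] - t0) * 1000 / nSegments,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  records <- records[order(records$segment, records$roi), ]
  rownames(records) <- NULL
  if (!is.null(logFile)) {
    hdr <- !file.exists(logFile)
    lines <- sprintf("%s\t%d\t%s\t%.6e\t%.4f\t%.4f\t%.2f",
                     format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"),
                     records$segment, records$roi, records$raw, records$z,
                     records$gauge, records$procMs)
    if (hdr) lines <- c("timestamp\tsegment\troi\traw\tz\tgauge\tprocMs", lines)
    cat(lines, file = logFile, sep = "\n", append = !hdr)
  }
  new("AlphaPowerSeries", records = records, baseline = baseline,
      segmentSamples = as.integer(segmentSamples),
      samplingRate = samplingRate, runId = runId)
}

#' @rdname accessors
#' @export
setMethod("records", "AlphaPowerSeries", function(x) x@records)

setMethod("show", "AlphaPowerSeries", function(object) {
  nseg <- length(unique(object@records$segment))
  cat(sprintf("AlphaPowerSeries '%s': %d segments x %d ROI(s) (%.1f s at %g ms/update)\n",
              object@runId, nseg, length(object@baseline),
              nseg * object@segmentSamples / object@samplingRate,
              1000 * object@segmentSamples / object@samplingRate))
  for (roi in names(object@baseline)) {
    bl <- object@baseline[[roi]]
    cat(sprintf("  %s baseline: mean %.4e, sd %.4e (n = %d)\n",
                roi, bl$mean, bl$sd, bl$n))
  }
})

setMethod("show", "SegmentSpectrum", function(object) {
  cat(sprintf("SegmentSpectrum: %d channels x %d bins (%.3g-Hz spacing), segment start %d\n",
              nrow(object@coefficients), ncol(object@coefficients),
              object@frequencies[2] - object@frequencies[1], object@startIndex))
})
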