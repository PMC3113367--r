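## Online-versus-offline comparison: rebuild the forward and inverse models
## at each run's own head position, re-run the identical segment/FFT/power/
## Z-score chain on the recorded stream, and compare the Z-scored alpha-power
## series by RMS percentage difference; sweep simulated head displacements.

#' Rigid head position
#'
#' A rigid transform (rotation then translation) of the head/source frame
#' relative to the fixed sensor frame, as measured at the start of a run.
#'
#' @param runId run identifier.
#' @param translation 3-vector, meters.
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1), or a unit
#'   quaternion of length 4 (w, x, y, z).
#' @return a \code{HeadPosition} list.
#' @export
headPosition <- function(runId = "run", translation = c(0, 0, 0),
                         rotation = diag(3)) {
  if (length(rotation) == 4L) rotation <- quaternionToRotation(rotation)
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(t(rotation) %*% rotation - diag(3))) > 1e-10 ||
      abs(det(rotation) - 1) > 1e-10)
    stopConfig("rotation must be orthonormal with determinant +1 (1e-10)")
  structure(list(runId = runId, translation = as.numeric(translation),
                 rotation = rotation), class = "HeadPosition")
}

#' @param q unit quaternion (w, x, y, z).
#' @rdname headPosition
#' @export
quaternionToRotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Apply a head position to the head-frame geometry
#'
#' Rigidly transforms dipole positions/orientations and scalp points into
#' the sensor frame: p -> R p + t (orientations rotate only). The sensor
#' array is left fixed.
#'
#' @param sources a \linkS4class{SourceSpace}.
#' @param scalp scalp point matrix.
#' @param position a \code{\link{headPosition}}.
#' @return list with transformed \code{sources} and \code{scalp}.
#' @export
applyHeadPosition <- function(sources, scalp, position) {
  R <- position$rotation; t <- position$translation
  list(
    sources = new("SourceSpace",
                  positions = sweep(sources@positions %*% t(R), 2, -t),
                  orientations = sources@orientations %*% t(R),
                  roi = sources@roi),
    scalp = sweep(scalp %*% t(R), 2, -t)
  )
}

#' Recompute the alpha-power series offline
#'
#' The optimal offline arm: for each run, rebuild the sphere fit, gain
#' matrix and imaging kernel at that run's measured head position, then
#' apply the identical segment / FFT / ROI-power / Z-score chain to the
#' recorded stream. Denoising (SSP projector and noise covariance) is
#' recomputed from the run's own baseline window unless the online objects
#' are passed in, which makes the two arms share denoising exactly.
#'
#' @param recordings character vector of per-run recording files (from
#'   \code{\link{recordingSink}}), in run order.
#' @param positions list of \code{\link{headPosition}} objects, one per run.
#' @param fixture the geometry fixture from \code{\link{makeFixture}}
#'   (head-frame sources and scalp).
#' @param ssp,noise optional online \linkS4class{SspProjector} /
#'   \linkS4class{NoiseCovariance} to reuse; \code{NULL} recomputes each
#'   from the run's baseline window.
#' @param snr,gamma,band,segmentSamples,nFft,baselineSegments pipeline
#'   parameters, defaults as in the online arm.
#' @param sspK SSP component count when recomputing.
#' @return list of \linkS4class{AlphaPowerSeries}, one per run.
#' @export
recomputeOffline <- function(recordings, positions, fixture,
                             ssp = NULL, noise = NULL, snr = 3, gamma = 0.5,
                             band = c(8, 13), segmentSamples = 500L,
                             nFft = 1000L, baselineSegments = 40L,
                             sspK = 2L) {
  if (length(positions) != length(recordings))
    stopConfig(sprintf("missing head position: %d recordings but %d positions",
                       length(recordings), length(positions)))
  lapply(seq_along(recordings), function(r) {
    moved <- applyHeadPosition(fixture$sources, fixture$scalp, positions[[r]])
    spheres <- fitSpheres(moved$scalp, fixture$sensors)
    gain <- computeGain(moved$sources, fixture$sensors, spheres)
    buffer <- replayRecording(recordings[[r]])
    hdr <- getHeader(buffer)
    nMeg <- nrow(values(gain))
    base <- getData(buffer, 0, baselineSegments * segmentSamples)@values
    base <- base[seq_len(nMeg), , drop = FALSE]
    rownames(base) <- channelLabels(gain)
    runSsp <- if (is.null(ssp)) computeSsp(base, sspK) else ssp
    runNoise <- if (is.null(noise))
      estimateNoiseCovariance(applySsp(runSsp, base), hdr@samplingRate)
    else noise
    kernel <- computeWmneKernel(gain, runNoise, runSsp, snr = snr,
                                gamma = gamma)
    runRealtimeLoop(buffer, kernel, nMegChannels = nMeg,
                    startSample = 0, nSegments = NULL,
                    segmentSamples = segmentSamples, nFft = nFft,
                    band = band, baselineSegments = baselineSegments,
                    samplingRate = hdr@samplingRate,
                    runId = sprintf("offline-%s", positions[[r]]$runId))
  })
}

#' RMS percentage difference between two Z-scored series
#'
#' \code{100 * ||online - offline|| / ||offline||} on the Z-scored series
#' (the offline arm normalizes). The measure is asymmetric in its arguments
#' through the normalizer only.
#'
#' @param online,offline numeric vectors of equal length >= 2.
#' @return percentage (>= 0).
#' @examples
#' rmsPercentDifference(1.1 * c(1, -2, 3), c(1, -2, 3))  # exactly 10
#' @export
rmsPercentDifference <- function(online, offline) {
  if (length(online) != length(offline) || length(online) < 2)
    stopConfig("series must have equal length >= 2")
  denom <- sqrt(sum(offline^2))
  if (denom == 0) stopConfig("offline series has zero norm")
  100 * sqrt(sum((online - offline)^2)) / denom
}

## Z-score column of one ROI from a series, in segment order
seriesZ <- function(series, roi = "PO") {
  r <- records(series)
  r$z[r$roi == roi][order(r$segment[r$roi == roi])]
}

#' Head-displacement sensitivity sweep
#'
#' Re-runs the offline arm with the head rigidly displaced along a
#' posterior-superior axis by each grid value and reports the RMS percentage
#' difference between the online series and each displaced offline series.
#' At 0 mm (identical geometry and shared denoising) the two arms collapse
#' (RMS% < 1); the error grows with displacement. The default grid tops out
#' at 12.5 mm, the maximum head displacement observed in the emulated
#' recording session.
#'
#' @param onlineSeries list of online \linkS4class{AlphaPowerSeries} per run.
#' @param recordings per-run recording files.
#' @param fixture geometry fixture (head frame).
#' @param ssp,noise the online denoising objects (shared by every sweep
#'   point, so geometry is the only difference).
#' @param displacementsMm displacement grid in millimeters; must include 0.
#' @param axis displacement direction (default posterior-superior).
#' @param roi ROI whose Z-series is compared (default "PO").
#' @param ... further pipeline parameters passed to
#'   \code{\link{recomputeOffline}}.
#' @return data.frame with columns \code{displacementMm} and
#'   \code{rmsPercent} (one row per grid point), with the per-run reports in
#'   attribute \code{"reports"}.
#' @export
headMovementSweep <- function(onlineSeries, recordings, fixture, ssp, noise,
                              displacementsMm = c(0, 2.5, 5, 7.5, 10, 12.5),
                              axis = c(0, -1, 1) / sqrt(2), roi = "PO", ...) {
  if (!any(displacementsMm == 0))
    stopConfig("displacement grid must include 0")
  dots <- list(...)
  segmentSamples <- dots$segmentSamples %||% 500L
  nFft <- dots$nFft %||% 1000L
  band <- dots$band %||% c(8, 13)
  baselineSegments <- dots$baselineSegments %||% 40L
  snr <- dots$snr %||% 3
  gamma <- dots$gamma %||% 0.5
  onlineZ <- lapply(onlineSeries, seriesZ, roi = roi)
  nMeg <- length(noise@variances)
  ## the recorded spectra do not depend on the candidate head position:
  ## replay and FFT each run once, reuse across the whole grid
  runSpectra <- lapply(recordings, function(path) {
    buffer <- replayRecording(path)
    hdr <- getHeader(buffer)
    nSeg <- nSamplesWritten(buffer) %/% segmentSamples
    lapply(seq_len(nSeg) - 1L, function(k) {
      seg <- getData(buffer, k * segmentSamples,
                     (k + 1) * segmentSamples)@values[seq_len(nMeg), ,
                                                      drop = FALSE]
      sp <- segmentFft(seg, nFft, hdr@samplingRate)
      sp@startIndex <- k * segmentSamples
      sp
    })
  })
  reports <- lapply(displacementsMm, function(d) {
    pos <- headPosition("sweep", translation = d / 1000 * axis)
    moved <- applyHeadPosition(fixture$sources, fixture$scalp, pos)
    spheres <- fitSpheres(moved$scalp, fixture$sensors)
    gain <- computeGain(moved$sources, fixture$sensors, spheres)
    kernel <- computeWmneKernel(gain, noise, ssp, snr = snr, gamma = gamma)
    offline <- lapply(seq_along(runSpectra), function(r)
      powerSeriesFromSpectra(runSpectra[[r]], kernel, band = band,
                             baselineSegments = baselineSegments,
                             segmentSamples = segmentSamples,
                             runId = sprintf("offline-%gmm-run%d", d, r)))
    offlineZ <- lapply(offline, seriesZ, roi = roi)
    perRun <- vapply(seq_along(onlineZ), function(r)
      rmsPercentDifference(onlineZ[[r]], offlineZ[[r]]), numeric(1))
    list(displacementMm = d,
         rmsPercent = rmsPercentDifference(unlist(onlineZ), unlist(offlineZ)),
         perRun = perRun, offline = offline)
  })
  out <- data.frame(
    displacementMm = displacementsMm,
    rmsPercent = vapply(reports, `[[`, numeric(1), "rmsPercent"))
  attr(out, "reports") <- reports
  out
}
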