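#' @import methods
NULL

## ---------------------------------------------------------------------------
## Real-time buffer objects
## ---------------------------------------------------------------------------

#' Buffer header: stream metadata
#'
#' Metadata describing the sample stream held by a \linkS4class{MegBuffer}:
#' channel count, sampling rate, channel labels and the wire value type.
#' The sample/event counters (\code{nSamples}, \code{nEvents}) are filled in
#' by \code{\link{getHeader}}; they are 0 in a freshly constructed header.
#'
#' @slot nChannels integer, number of channels (> 0).
#' @slot samplingRate numeric, sampling rate in Hz (> 0).
#' @slot channelLabels character vector of length \code{nChannels}.
#' @slot dataType one of \code{"int16"}, \code{"int32"}, \code{"float32"},
#'   \code{"float64"}: the value type used on the wire and in recordings.
#' @slot nSamples,nEvents numeric counters (monotone between header resets).
#' @seealso \code{\link{bufferHeader}}, \code{\link{megBuffer}}
#' @exportClass BufferHeader
setClass("BufferHeader",
  representation(
    nChannels = "integer",
    samplingRate = "numeric",
    channelLabels = "character",
    dataType = "character",
    nSamples = "numeric",
    nEvents = "numeric"
  )
)

setValidity("BufferHeader", function(object) {
  msg <- character()
  if (length(object@channelLabels) != object@nChannels)
    msg <- c(msg, "channelLabels length must equal nChannels")
  if (!object@dataType %in% c("int16", "int32", "float32", "float64"))
    msg <- c(msg, "dataType must be one of int16, int32, float32, float64")
  if (object@nSamples < 0 || object@nEvents < 0)
    msg <- c(msg, "sample/event counters must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Contiguous block of samples
#'
#' A block of consecutive samples as returned by \code{\link{getData}}:
#' a channels-by-samples matrix plus the 0-based global index of its first
#' column. All sample ranges in the package are half-open \code{[begin, end)}.
#'
#' @slot values numeric matrix, channels in rows, consecutive samples in columns.
#' @slot firstSampleIndex 0-based global index of column 1.
#' @exportClass SampleBlock
setClass("SampleBlock",
  representation(values = "matrix", firstSampleIndex = "numeric")
)

setValidity("SampleBlock", function(object) {
  if (object@firstSampleIndex < 0) "firstSampleIndex must be >= 0" else TRUE
})

#' Timestamped buffer event
#'
#' An event (e.g. a stimulus trigger) anchored to a global sample index.
#'
#' @slot sample 0-based global sample index the event refers to.
#' @slot type event type string, e.g. \code{"trigger"}.
#' @slot value event value: an integer or a string.
#' @exportClass BufferEvent
setClass("BufferEvent",
  representation(sample = "numeric", type = "character", value = "ANY")
)

setValidity("BufferEvent", function(object) {
  msg <- character()
  if (object@sample < 0) msg <- c(msg, "sample must be >= 0")
  if (!(is.numeric(object@value) || is.character(object@value)) ||
      length(object@value) != 1L)
    msg <- c(msg, "value must be a single integer or string")
  if (length(msg)) msg else TRUE
})

#' Real-time sample buffer
#'
#' A FieldTrip-style real-time buffer: one header, a growing channels-by-samples
#' matrix and an ordered event list. The buffer is a mutable object (its state
#' lives in an environment) so that an acquisition writer and analysis readers
#' can share one instance; \code{\link{serveBuffer}} exposes the same instance
#' over TCP. The most recent \code{capacity} samples are retained (ring
#' semantics); reads into evicted history raise a distinct error.
#'
#' @slot state environment holding header, retained blocks, events and counters.
#' @seealso \code{\link{megBuffer}}, \code{\link{putHeader}},
#'   \code{\link{putData}}, \code{\link{getData}}, \code{\link{waitForSamples}},
#'   \code{\link{putEvent}}, \code{\link{getEvents}}
#' @exportClass MegBuffer
setClass("MegBuffer", representation(state = "environment"))

## ---------------------------------------------------------------------------
## Geometry / forward-model objects
## ---------------------------------------------------------------------------

#' Synthetic Elekta-like sensor array
#'
#' 102 sensor sites on a helmet-like spherical cap, each carrying one
#' magnetometer (reads the field component along the site normal) and two
#' orthogonal planar gradiometers (read the spatial derivative of that
#' component along two tangential directions, separated by a 16.8-mm
#' baseline), for 306 MEG channels, plus integer-valued trigger channels.
#'
#' @slot sitePositions 102 x 3 matrix, site centers in the head frame (m).
#' @slot siteNormals 102 x 3 matrix of outward unit normals.
#' @slot channels data.frame with one row per MEG channel: \code{label},
#'   \code{site} (1-based site index), \code{kind} ("mag" or "grad"),
#'   \code{dirX/Y/Z} (unit measurement direction), \code{baseline} (m, 0 for
#'   magnetometers), \code{calibration} (physical units per raw unit).
#' @slot triggerLabels labels of the integer-valued trigger channels.
#' @seealso \code{\link{makeFixture}}
#' @exportClass SensorArray
setClass("SensorArray",
  representation(
    sitePositions = "matrix",
    siteNormals = "matrix",
    channels = "data.frame",
    triggerLabels = "character"
  )
)

setValidity("SensorArray", function(object) {
  msg <- character()
  ns <- nrow(object@sitePositions)
  if (!identical(dim(object@siteNormals), c(ns, 3L)) ||
      ncol(object@sitePositions) != 3L)
    msg <- c(msg, "sitePositions and siteNormals must be n x 3 matrices")
  if (nrow(object@channels) != 3L * ns)
    msg <- c(msg, "need exactly 3 channels (1 mag + 2 grad) per site")
  perSite <- table(factor(object@channels$kind,
                          levels = c("mag", "grad")),
                   object@channels$site)
  if (ns > 0 && (!all(perSite["mag", ] == 1) || !all(perSite["grad", ] == 2)))
    msg <- c(msg, "each site must carry exactly 1 magnetometer and 2 gradiometers")
  nrm <- sqrt(rowSums(object@siteNormals^2))
  dirs <- as.matrix(object@channels[, c("dirX", "dirY", "dirZ")])
  if (any(abs(nrm - 1) > 1e-12) ||
      any(abs(sqrt(rowSums(dirs^2)) - 1) > 1e-12))
    msg <- c(msg, "normals and measurement directions must be unit vectors (1e-12)")
  if (length(msg)) msg else TRUE
})

#' Cortical source space with ROI labels
#'
#' Fixed-orientation current dipoles tiling two cortical patches: a
#' parieto-occipital patch (label \code{"PO"}) and a prefrontal patch
#' (\code{"PFC"}). Orientations are approximately surface-normal but are
#' guaranteed a tangential component of norm >= 0.3 with respect to the head
#' center, because purely radial dipoles are magnetically silent in a
#' spherically symmetric conductor.
#'
#' @slot positions n x 3 matrix of dipole positions (m, head frame).
#' @slot orientations n x 3 matrix of unit dipole orientations.
#' @slot roi factor of ROI labels ("PO"/"PFC"), one per dipole.
#' @seealso \code{\link{makeFixture}}, \code{\link{computeGain}}
#' @exportClass SourceSpace
setClass("SourceSpace",
  representation(positions = "matrix", orientations = "matrix", roi = "factor")
)

setValidity("SourceSpace", function(object) {
  msg <- character()
  n <- nrow(object@positions)
  if (!identical(dim(object@orientations), c(n, 3L)) ||
      ncol(object@positions) != 3L)
    msg <- c(msg, "positions and orientations must be n x 3 matrices")
  if (length(object@roi) != n)
    msg <- c(msg, "roi must have one label per dipole")
  if (n > 0 && any(abs(sqrt(rowSums(object@orientations^2)) - 1) > 1e-12))
    msg <- c(msg, "orientations must be unit vectors (1e-12)")
  if (length(msg)) msg else TRUE
})

#' Overlapping-sphere head model
#'
#' One conducting sphere per sensor site, least-squares fitted to the scalp
#' points with Gaussian weights concentrated near that site (the
#' overlapping-sphere analytic approach). With uniform weights the model
#' degenerates to the single best-fit sphere.
#'
#' @slot centers nSites x 3 matrix of sphere centers (m).
#' @slot radii numeric vector of sphere radii (m).
#' @slot residuals per-site weighted RMS distance of scalp points to the
#'   fitted sphere surface (m).
#' @seealso \code{\link{fitSpheres}}
#' @exportClass SphereModel
setClass("SphereModel",
  representation(centers = "matrix", radii = "numeric", residuals = "numeric")
)

setValidity("SphereModel", function(object) {
  msg <- character()
  if (ncol(object@centers) != 3L) msg <- c(msg, "centers must be n x 3")
  if (length(object@radii) != nrow(object@centers))
    msg <- c(msg, "one radius per center")
  if (any(!is.finite(object@centers)) || any(!is.finite(object@radii)) ||
      any(object@radii <= 0))
    msg <- c(msg, "centers and radii must be finite, radii > 0")
  if (length(msg)) msg else TRUE
})

#' Forward gain matrix (lead field)
#'
#' The linear map from unit dipole moments (A m) along the fixed source
#' orientations to MEG channel readings (T for magnetometers, T/m for planar
#' gradiometers). Row order is bound to the \linkS4class{SensorArray} channel
#' table, column order to the \linkS4class{SourceSpace} dipole listing.
#'
#' @slot values nChannels x nDipoles numeric matrix.
#' @slot channelLabels character, one per row.
#' @slot roi factor of dipole ROI labels, one per column.
#' @seealso \code{\link{computeGain}}
#' @exportClass GainMatrix
setClass("GainMatrix",
  representation(values = "matrix", channelLabels = "character", roi = "factor")
)

setValidity("GainMatrix", function(object) {
  msg <- character()
  if (length(object@channelLabels) != nrow(object@values))
    msg <- c(msg, "one channel label per row")
  if (length(object@roi) != ncol(object@values))
    msg <- c(msg, "one ROI label per column")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "gain entries must be finite")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Denoising / inverse objects
## ---------------------------------------------------------------------------

#' Signal-space projection operator
#'
#' SSP removes environmental interference by projecting sensor vectors onto
#' the orthogonal complement of a k-dimensional interference subspace
#' estimated from interference-dominated data: P = I - U U', with U the top-k
#' left singular vectors of the (channel-mean-removed) segment.
#'
#' @slot u nChannels x k orthonormal interference subspace basis.
#' @slot p nChannels x nChannels projector matrix, symmetric and idempotent.
#' @slot k integer component count (k = 0 gives the identity).
#' @seealso \code{\link{computeSsp}}
#' @exportClass SspProjector
setClass("SspProjector",
  representation(u = "matrix", p = "matrix", k = "integer")
)

setValidity("SspProjector", function(object) {
  msg <- character()
  n <- nrow(object@p)
  if (ncol(object@p) != n) msg <- c(msg, "projector must be square")
  if (ncol(object@u) != object@k) msg <- c(msg, "u must have k columns")
  if (object@k > 0 && nrow(object@u) != n)
    msg <- c(msg, "u rows must match projector dimension")
  if (max(abs(object@p - t(object@p))) > 1e-10)
    msg <- c(msg, "projector must be symmetric (1e-10)")
  if (max(abs(object@p %*% object@p - object@p)) > 1e-10)
    msg <- c(msg, "projector must be idempotent (1e-10)")
  if (length(msg)) msg else TRUE
})

#' Diagonal per-channel noise covariance
#'
#' Per-channel sample variances of an SSP-cleaned baseline segment, in
#' squared channel measurement units. A diagonal model is used because the
#' baseline run is short (10 s).
#'
#' @slot variances named numeric vector, all > 0.
#' @slot segmentId free-text identifier of the source segment.
#' @seealso \code{\link{estimateNoiseCovariance}}
#' @exportClass NoiseCovariance
setClass("NoiseCovariance",
  representation(variances = "numeric", segmentId = "character")
)

setValidity("NoiseCovariance", function(object) {
  if (any(!is.finite(object@variances)) || any(object@variances <= 0))
    "all variances must be finite and > 0" else TRUE
})

#' Precomputed linear imaging kernel (WMNE)
#'
#' The depth-weighted, cortically constrained minimum-norm inverse operator,
#' restricted to the target ROIs and stored with SSP and noise whitening
#' folded in, so that source spectra/time series are obtained from raw sensor
#' data by a single matrix product. Rows follow the \linkS4class{SourceSpace}
#' ROI listing.
#'
#' @slot values nSelectedSources x nChannels matrix.
#' @slot lambda2 Tikhonov regularization parameter (1/snr^2).
#' @slot gamma depth-weighting exponent.
#' @slot snr assumed amplitude signal-to-noise ratio.
#' @slot sourceIndex integer indices of the retained sources in the full
#'   source space.
#' @slot roi factor of ROI labels, one per kernel row.
#' @slot gainFingerprint,noiseFingerprint content fingerprints of the gain
#'   matrix and noise covariance the kernel was built from (provenance).
#' @seealso \code{\link{computeWmneKernel}}, \code{\link{roiAlphaPower}}
#' @exportClass ImagingKernel
setClass("ImagingKernel",
  representation(
    values = "matrix",
    lambda2 = "numeric",
    gamma = "numeric",
    snr = "numeric",
    sourceIndex = "integer",
    roi = "factor",
    gainFingerprint = "character",
    noiseFingerprint = "character"
  )
)

setValidity("ImagingKernel", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@sourceIndex) ||
      nrow(object@values) != length(object@roi))
    msg <- c(msg, "one source index and ROI label per kernel row")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "kernel entries must be finite")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Real-time pipeline objects
## ---------------------------------------------------------------------------

#' One-sided FFT of a sensor segment
#'
#' Fourier coefficients of a rectangular-windowed, zero-padded sensor
#' segment. Bin spacing is samplingRate / nFft; nBins = nFft/2 + 1.
#'
#' @slot coefficients complex nChannels x nBins matrix.
#' @slot frequencies bin frequencies in Hz.
#' @slot startIndex 0-based global index of the segment's first sample.
#' @slot samplingRate Hz.
#' @slot segmentSamples number of (un-padded) samples in the segment.
#' @seealso \code{\link{segmentFft}}
#' @exportClass SegmentSpectrum
setClass("SegmentSpectrum",
  representation(
    coefficients = "matrix",
    frequencies = "numeric",
    startIndex = "numeric",
    samplingRate = "numeric",
    segmentSamples = "integer"
  )
)

setValidity("SegmentSpectrum", function(object) {
  msg <- character()
  if (!is.complex(object@coefficients))
    msg <- c(msg, "coefficients must be complex")
  if (length(object@frequencies) != ncol(object@coefficients))
    msg <- c(msg, "one frequency per coefficient column")
  if (length(msg)) msg else TRUE
})

#' Per-segment ROI alpha-power series
#'
#' One record per 500-ms segment per ROI: raw alpha power (the sum of Fourier
#' coefficient magnitudes over the 8-13 Hz bins and all ROI sources), the
#' Z-score against the run's frozen 20-s baseline, and the inverse-power
#' feedback gauge. Baseline statistics (mean, SD, n) are stored per ROI.
#'
#' @slot records data.frame with columns \code{segment} (0-based index),
#'   \code{startIndex}, \code{roi}, \code{raw}, \code{z}, \code{gauge},
#'   \code{state} (paradigm state if known) and \code{procMs}.
#' @slot baseline named list (by ROI) of \code{list(mean, sd, n)}.
#' @slot segmentSamples,samplingRate segmentation parameters.
#' @slot runId free-text run identifier.
#' @seealso \code{\link{runRealtimeLoop}}
#' @exportClass AlphaPowerSeries
setClass("AlphaPowerSeries",
  representation(
    records = "data.frame",
    baseline = "list",
    segmentSamples = "integer",
    samplingRate = "numeric",
    runId = "character"
  )
)

setValidity("AlphaPowerSeries", function(object) {
  need <- c("segment", "startIndex", "roi", "raw", "z", "gauge")
  if (!all(need %in% names(object@records)))
    paste("records must contain columns:", paste(need, collapse = ", "))
  else TRUE
})
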