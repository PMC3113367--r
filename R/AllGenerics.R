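#' @rdname putHeader
#' @export
setGeneric("putHeader", function(buffer, header) standardGeneric("putHeader"))

#' @rdname getHeader
#' @export
setGeneric("getHeader", function(buffer) standardGeneric("getHeader"))

#' @rdname putData
#' @export
setGeneric("putData", function(buffer, values) standardGeneric("putData"))

#' @rdname getData
#' @export
setGeneric("getData", function(buffer, begin, end) standardGeneric("getData"))

#' @rdname waitForSamples
#' @export
setGeneric("waitForSamples", function(buffer, minTotal, timeoutMs)
  standardGeneric("waitForSamples"))

#' @rdname putEvent
#' @export
setGeneric("putEvent", function(buffer, event) standardGeneric("putEvent"))

#' @rdname getEvents
#' @export
setGeneric("getEvents", function(buffer, begin, end) standardGeneric("getEvents"))

#' @rdname bufferAccessors
#' @export
setGeneric("nSamplesWritten", function(x) standardGeneric("nSamplesWritten"))

#' @rdname bufferAccessors
#' @export
setGeneric("nEventsWritten", function(x) standardGeneric("nEventsWritten"))

#' Accessors for toolkit objects
#'
#' \code{values} extracts the numeric payload of a matrix-like object
#' (\linkS4class{SampleBlock}, \linkS4class{GainMatrix},
#' \linkS4class{ImagingKernel}); \code{nChannels}, \code{samplingRate},
#' \code{channelLabels} read stream metadata; \code{nDipoles} and
#' \code{roiLabels} describe a \linkS4class{SourceSpace} (or the per-row /
#' per-column binding of a kernel or gain matrix); \code{firstSampleIndex}
#' gives a block's 0-based global start; \code{records} extracts the
#' per-segment data.frame of an \linkS4class{AlphaPowerSeries}.
#'
#' @param x the object.
#' @return the corresponding slot value.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname accessors
#' @export
setGeneric("nDipoles", function(x) standardGeneric("nDipoles"))

#' @rdname accessors
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))

#' @rdname accessors
#' @export
setGeneric("firstSampleIndex", function(x) standardGeneric("firstSampleIndex"))

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
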