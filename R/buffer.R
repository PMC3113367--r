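#' Create a buffer header
#'
#' @param nChannels number of channels (positive integer).
#' @param samplingRate sampling rate in Hz (positive).
#' @param channelLabels optional character vector of length \code{nChannels};
#'   defaults to \code{CH001, CH002, ...}.
#' @param dataType wire value type: \code{"int16"}, \code{"int32"},
#'   \code{"float32"} or \code{"float64"}.
#' @return a \linkS4class{BufferHeader}.
#' @examples
#' hdr <- bufferHeader(309, 1000)
#' nChannels(hdr)
#' @export
bufferHeader <- function(nChannels, samplingRate,
                         channelLabels = NULL, dataType = "float32") {
  if (!isScalarNumber(nChannels) || nChannels <= 0 ||
      nChannels != round(nChannels))
    stopProtocol("nChannels must be a positive integer")
  if (!isScalarNumber(samplingRate) || samplingRate <= 0)
    stopProtocol("samplingRate must be a positive number")
  nChannels <- as.integer(nChannels)
  if (is.null(channelLabels))
    channelLabels <- sprintf("CH%03d", seq_len(nChannels))
  new("BufferHeader",
      nChannels = nChannels, samplingRate = as.numeric(samplingRate),
      channelLabels = as.character(channelLabels),
      dataType = dataType, nSamples = 0, nEvents = 0)
}

#' Create a real-time sample buffer
#'
#' @param capacity ring capacity: the number of most recent samples retained
#'   (default 600000, i.e. 10 minutes at 1 kHz). Older samples are evicted;
#'   reading them raises an eviction error.
#' @return an empty \linkS4class{MegBuffer} (no header yet).
#' @examples
#' buf <- megBuffer()
#' putHeader(buf, bufferHeader(4, 1000))
#' putData(buf, matrix(rnorm(4 * 29), 4, 29))
#' nSamplesWritten(buf)
#' @export
megBuffer <- function(capacity = 600000) {
  if (!isScalarNumber(capacity) || capacity < 1)
    stopConfig("capacity must be a positive number of samples")
  state <- new.env(parent = emptyenv())
  state$header <- NULL
  state$blocks <- list()
  state$blockStart <- numeric(0)
  state$total <- 0
  state$oldest <- 0      # global index of the oldest retained sample
  state$events <- list()
  state$nEvents <- 0
  state$capacity <- capacity
  new("MegBuffer", state = state)
}

requireHeader <- function(buffer) {
  if (is.null(buffer@state$header))
    stopProtocol("no header has been put to the buffer")
  invisible(buffer@state$header)
}

#' Install a header, resetting the buffer
#'
#' Installing a header discards all previously held samples and events and
#' resets both counters to 0 (header-reset semantics). An invalid header
#' (non-positive channel count or sampling rate) is rejected with a protocol
#' error.
#'
#' @param buffer a \linkS4class{MegBuffer}.
#' @param header a \linkS4class{BufferHeader}.
#' @return the buffer, invisibly.
#' @rdname putHeader
#' @export
setMethod("putHeader", signature("MegBuffer", "BufferHeader"),
  function(buffer, header) {
    if (header@nChannels <= 0) stopProtocol("header nChannels must be > 0")
    if (header@samplingRate <= 0) stopProtocol("header samplingRate must be > 0")
    s <- buffer@state
    s$header <- header
    s$blocks <- list()
    s$blockStart <- numeric(0)
    s$total <- 0
    s$oldest <- 0
    s$events <- list()
    s$nEvents <- 0
    invisible(buffer)
  })

#' Read the current header
#'
#' @param buffer a \linkS4class{MegBuffer}.
#' @return the installed \linkS4class{BufferHeader} with its \code{nSamples}
#'   and \code{nEvents} counters filled in.
#' @rdname getHeader
#' @export
setMethod("getHeader", "MegBuffer", function(buffer) {
  hdr <- requireHeader(buffer)
  hdr@nSamples <- buffer@state$total
  hdr@nEvents <- buffer@state$nEvents
  hdr
})

#' Append a block of samples
#'
#' Appends \code{ncol(values)} consecutive samples. The row count must match
#' the header's channel count. Appending is atomic: readers never observe a
#' partially written block.
#'
#' @param buffer a \linkS4class{MegBuffer}.
#' @param values numeric matrix, channels x samples. A zero-column matrix is
#'   acknowledged and leaves the buffer unchanged.
#' @return the new total sample count, invisibly.
#' @rdname putData
#' @export
setMethod("putData", signature("MegBuffer", "matrix"), function(buffer, values) {
  hdr <- requireHeader(buffer)
  if (nrow(values) != hdr@nChannels)
    stopProtocol(sprintf("block has %d rows but header declares %d channels",
                         nrow(values), hdr@nChannels))
  s <- buffer@state
  if (ncol(values) > 0) {
    s$blocks[[length(s$blocks) + 1L]] <- values
    s$blockStart <- c(s$blockStart, s$total)
    s$total <- s$total + ncol(values)
    ## evict whole blocks that fell out of the retention window
    limit <- s$total - s$capacity
    while (length(s$blocks) > 1L && s$blockStart[2L] <= limit) {
      s$blocks <- s$blocks[-1L]
      s$blockStart <- s$blockStart[-1L]
    }
    s$oldest <- s$blockStart[1L]
  }
  invisible(s$total)
})

#' Read a range of samples
#'
#' Returns exactly the columns written for the half-open global index range
#' \code{[begin, end)}, bit-identical to what was put. Reading past the write
#' pointer raises a "not yet available" error (condition class
#' \code{megstreamNotAvailableError}), distinct from a malformed-request
#' protocol error; reading into evicted ring history raises
#' \code{megstreamEvictedError}.
#'
#' @param buffer a \linkS4class{MegBuffer}.
#' @param begin,end 0-based half-open global sample range, \code{begin <= end}.
#' @return a \linkS4class{SampleBlock}.
#' @rdname getData
#' @export
setMethod("getData", "MegBuffer", function(buffer, begin, end) {
  hdr <- requireHeader(buffer)
  if (!isScalarNumber(begin) || !isScalarNumber(end) ||
      begin < 0 || end < begin)
    stopProtocol("need 0 <= begin <= end")
  s <- buffer@state
  if (end > s$total)
    stopNotAvailable(sprintf(
      "requested samples up to %d but only %d written", end, s$total))
  if (begin == end)
    return(new("SampleBlock",
               values = matrix(0, hdr@nChannels, 0), firstSampleIndex = begin))
  if (begin < s$oldest)
    stopEvicted(sprintf(
      "samples before %d have been evicted from the ring", s$oldest))
  ## gather the covering blocks
  out <- matrix(0, hdr@nChannels, end - begin)
  for (i in seq_along(s$blocks)) {
    b0 <- s$blockStart[i]
    b1 <- b0 + ncol(s$blocks[[i]])
    if (b1 <= begin || b0 >= end) next
    src <- max(begin, b0)
    dst <- min(end, b1)
    out[, (src - begin + 1L):(dst - begin)] <-
      s$blocks[[i]][, (src - b0 + 1L):(dst - b0), drop = FALSE]
  }
  new("SampleBlock", values = out, firstSampleIndex = begin)
})

#' Wait until a sample count is reached
#'
#' Returns as soon as the buffer holds at least \code{minTotal} samples, or at
#' \code{timeoutMs} milliseconds, whichever comes first; never blocks past the
#' timeout. With an in-process writer the condition is usually already
#' satisfied; with a remote writer this polls.
#'
#' @param buffer a \linkS4class{MegBuffer}.
#' @param minTotal the sample count waited for.
#' @param timeoutMs timeout in milliseconds (>= 0).
#' @return the current total sample count (which may be below \code{minTotal}
#'   if the timeout expired).
#' @rdname waitForSamples
#' @export
setMethod("waitForSamples", "MegBuffer", function(buffer, minTotal, timeoutMs) {
  requireHeader(buffer)
  if (!isScalarNumber(timeoutMs) || timeoutMs < 0)
    stopProtocol("timeoutMs must be >= 0")
  s <- buffer@state
  deadline <- Sys.time() + timeoutMs / 1000
  repeat {
    if (s$total >= minTotal || Sys.time() >= deadline) return(s$total)
    Sys.sleep(min(0.005, timeoutMs / 1000))
  }
})

#' Append / read events
#'
#' Events are returned in insertion order and round-trip identically. An
#' event whose sample index lies beyond the written samples is rejected.
#'
#' @param buffer a \linkS4class{MegBuffer}.
#' @param event a \linkS4class{BufferEvent}.
#' @return \code{putEvent}: the new event count, invisibly.
#' @rdname putEvent
#' @export
setMethod("putEvent", signature("MegBuffer", "BufferEvent"),
  function(buffer, event) {
    requireHeader(buffer)
    s <- buffer@state
    if (event@sample > s$total)
      stopProtocol(sprintf(
        "event sample %d beyond written samples (%d)", event@sample, s$total))
    s$events[[length(s$events) + 1L]] <- event
    s$nEvents <- s$nEvents + 1
    invisible(s$nEvents)
  })

#' @param begin,end 0-based half-open event index range within
#'   \code{[0, nEventsWritten]}.
#' @return \code{getEvents}: a list of \linkS4class{BufferEvent}.
#' @rdname putEvent
#' @aliases getEvents
#' @export
setMethod("getEvents", "MegBuffer", function(buffer, begin, end) {
  requireHeader(buffer)
  s <- buffer@state
  if (!isScalarNumber(begin) || !isScalarNumber(end) ||
      begin < 0 || end < begin || end > s$nEvents)
    stopProtocol("event range must satisfy 0 <= begin <= end <= nEventsWritten")
  if (begin == end) return(list())
  s$events[(begin + 1L):end]
})

#' @rdname bufferAccessors
#' @param x a \linkS4class{MegBuffer}.
#' @return current sample / event counters.
#' @export
setMethod("nSamplesWritten", "MegBuffer", function(x) x@state$total)

#' @rdname bufferAccessors
#' @export
setMethod("nEventsWritten", "MegBuffer", function(x) x@state$nEvents)

#' Create a buffer event
#'
#' @param sample 0-based global sample index.
#' @param type event type string (default \code{"trigger"}).
#' @param value integer or string event value.
#' @return a \linkS4class{BufferEvent}.
#' @export
bufferEvent <- function(sample, type = "trigger", value = 1L) {
  new("BufferEvent", sample = as.numeric(sample), type = type, value = value)
}

## -- simple accessors --------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("values", "SampleBlock", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("firstSampleIndex", "SampleBlock", function(x) x@firstSampleIndex)
#' @rdname accessors
#' @export
setMethod("nChannels", "BufferHeader", function(x) x@nChannels)
#' @rdname accessors
#' @export
setMethod("samplingRate", "BufferHeader", function(x) x@samplingRate)
#' @rdname accessors
#' @export
setMethod("channelLabels", "BufferHeader", function(x) x@channelLabels)

setMethod("show", "MegBuffer", function(object) {
  s <- object@state
  if (is.null(s$header)) {
    cat("MegBuffer (no header)\n")
  } else {
    cat(sprintf("MegBuffer: %d channels @ %g Hz | %d samples (%d retained) | %d events\n",
                s$header@nChannels, s$header@samplingRate,
                s$total, s$total - s$oldest, s$nEvents))
  }
})

setMethod("show", "BufferHeader", function(object) {
  cat(sprintf("BufferHeader: %d channels @ %g Hz, %s, %d samples, %d events\n",
              object@nChannels, object@samplingRate, object@dataType,
              object@nSamples, object@nEvents))
})

setMethod("show", "SampleBlock", function(object) {
  cat(sprintf("SampleBlock: %d channels x %d samples, global [%d, %d)\n",
              nrow(object@values), ncol(object@values),
              object@firstSampleIndex,
              object@firstSampleIndex + ncol(object@values)))
})
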