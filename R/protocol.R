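## FieldTrip buffer wire protocol (v1 framing), little-endian throughout.
##
## Every message is an 8-byte header { uint16 version = 1, uint16 command,
## uint32 payloadBytes } followed by the payload. Commands follow the public
## FieldTrip numbering (PUT_HDR 0x101, PUT_DAT 0x102, PUT_EVT 0x103, GET_HDR
## 0x201, GET_DAT 0x202, GET_EVT 0x203, WAIT_DAT 0x402; *_OK / *_ERR
## responses 0x104/0x105, 0x204/0x205, 0x404/0x405).
##
## Dialect notes (where the public protocol is ambiguous or silent), see
## ?bufferProtocol.

FT_VERSION <- 1L
FT_PUT_HDR <- 0x101L; FT_PUT_DAT <- 0x102L; FT_PUT_EVT <- 0x103L
FT_PUT_OK  <- 0x104L; FT_PUT_ERR <- 0x105L
FT_GET_HDR <- 0x201L; FT_GET_DAT <- 0x202L; FT_GET_EVT <- 0x203L
FT_GET_OK  <- 0x204L; FT_GET_ERR <- 0x205L
FT_WAIT_DAT <- 0x402L; FT_WAIT_OK <- 0x404L; FT_WAIT_ERR <- 0x405L

## FieldTrip numeric type codes for the subset this buffer supports
ftTypeCode <- c(int16 = 6L, int32 = 7L, float32 = 9L, float64 = 10L)
ftTypeBytes <- c(int16 = 2L, int32 = 4L, float32 = 4L, float64 = 8L)

ftTypeName <- function(code) {
  nm <- names(ftTypeCode)[match(code, ftTypeCode)]
  if (is.na(nm)) stopProtocol(sprintf("unsupported wire data type code %d", code))
  nm
}

wU16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
wI32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
wF32 <- function(x) writeBin(as.numeric(x), raw(), size = 4, endian = "little")

encodeValues <- function(values, dataType) {
  v <- as.vector(values)
  switch(dataType,
    int16   = writeBin(as.integer(round(v)), raw(), size = 2, endian = "little"),
    int32   = writeBin(as.integer(round(v)), raw(), size = 4, endian = "little"),
    float32 = writeBin(as.numeric(v), raw(), size = 4, endian = "little"),
    float64 = writeBin(as.numeric(v), raw(), size = 8, endian = "little"),
    stopProtocol(sprintf("unsupported data type '%s'", dataType)))
}

decodeValues <- function(bytes, dataType, n) {
  switch(dataType,
    int16   = as.numeric(readBin(bytes, integer(), n = n, size = 2,
                                 endian = "little")),
    int32   = as.numeric(readBin(bytes, integer(), n = n, size = 4,
                                 endian = "little")),
    float32 = readBin(bytes, double(), n = n, size = 4, endian = "little"),
    float64 = readBin(bytes, double(), n = n, size = 8, endian = "little"))
}

ftMessage <- function(command, payload = raw(0)) {
  c(wU16(FT_VERSION), wU16(command), wI32(length(payload)), payload)
}

## cursor-based decoding over a raw vector
rawCursor <- function(bytes) {
  env <- new.env(parent = emptyenv()); env$bytes <- bytes; env$pos <- 0L; env
}
curTake <- function(cur, n) {
  if (cur$pos + n > length(cur$bytes))
    stopProtocol("truncated message payload")
  out <- cur$bytes[(cur$pos + 1L):(cur$pos + n)]
  cur$pos <- cur$pos + as.integer(n)
  out
}
curU16 <- function(cur) readBin(curTake(cur, 2L), integer(), size = 2,
                                signed = FALSE, endian = "little")
curI32 <- function(cur) readBin(curTake(cur, 4L), integer(), size = 4,
                                endian = "little")
curF32 <- function(cur) readBin(curTake(cur, 4L), double(), size = 4,
                                endian = "little")
curLeft <- function(cur) length(cur$bytes) - cur$pos

## -- header ------------------------------------------------------------------

encodeHeaderPayload <- function(header) {
  names <- c(writeBin(header@channelLabels, raw()))  # NUL-terminated each
  chunk <- c(wI32(1L), wI32(length(names)), names)   # chunk type 1: names
  c(wI32(header@nChannels), wI32(as.integer(header@nSamples)),
    wI32(as.integer(header@nEvents)), wF32(header@samplingRate),
    wI32(ftTypeCode[[header@dataType]]), wI32(length(chunk)), chunk)
}

decodeHeaderPayload <- function(bytes) {
  cur <- rawCursor(bytes)
  nchans <- curI32(cur); nsamp <- curI32(cur); nevt <- curI32(cur)
  fsample <- curF32(cur); dtype <- curI32(cur); chunkBytes <- curI32(cur)
  labels <- NULL
  end <- cur$pos + chunkBytes
  while (cur$pos < end) {
    ctype <- curI32(cur); csize <- curI32(cur)
    cdata <- curTake(cur, csize)
    if (ctype == 1L && length(cdata)) {
      ends <- which(cdata == as.raw(0L))
      starts <- c(1L, utils::head(ends, -1L) + 1L)
      labels <- mapply(function(s, e)
        if (e > s) rawToChar(cdata[s:(e - 1L)]) else "", starts, ends)
    }
  }
  hdr <- bufferHeader(nchans, fsample, channelLabels = labels,
                      dataType = ftTypeName(dtype))
  hdr@nSamples <- nsamp; hdr@nEvents <- nevt
  hdr
}

## -- data --------------------------------------------------------------------

## On the wire samples are stored sample-major (all channels of sample 1,
## then sample 2, ...), which is exactly R's column-major layout for a
## channels x samples matrix.
encodeDataPayload <- function(values, dataType) {
  body <- encodeValues(values, dataType)
  c(wI32(nrow(values)), wI32(ncol(values)), wI32(ftTypeCode[[dataType]]),
    wI32(length(body)), body)
}

decodeDataPayload <- function(bytes) {
  cur <- rawCursor(bytes)
  nchans <- curI32(cur); nsamp <- curI32(cur)
  dtype <- ftTypeName(curI32(cur)); nbytes <- curI32(cur)
  v <- decodeValues(curTake(cur, nbytes), dtype, nchans * nsamp)
  list(values = matrix(v, nrow = nchans, ncol = nsamp), dataType = dtype)
}

## -- events ------------------------------------------------------------------

encodeEventPayload <- function(event) {
  typeBytes <- charToRaw(event@type)
  if (is.character(event@value)) {
    valType <- 0L; valBytes <- charToRaw(event@value)
    valNumel <- length(valBytes)
  } else {
    valType <- 7L; valBytes <- wI32(event@value); valNumel <- 1L
  }
  c(wI32(0L), wI32(length(typeBytes)),      # type_type = CHAR, numel
    wI32(valType), wI32(valNumel),
    wI32(as.integer(event@sample)), wI32(0L), wI32(0L),  # sample, offset, duration
    wI32(length(typeBytes) + length(valBytes)), typeBytes, valBytes)
}

decodeEventsPayload <- function(bytes) {
  cur <- rawCursor(bytes)
  out <- list()
  while (curLeft(cur) > 0) {
    curI32(cur)                      # type_type (always CHAR here)
    typeNumel <- curI32(cur)
    valType <- curI32(cur); valNumel <- curI32(cur)
    sample <- curI32(cur); curI32(cur); curI32(cur)
    curI32(cur)                      # bufsize
    type <- rawToChar(curTake(cur, typeNumel))
    value <- if (valType == 0L) rawToChar(curTake(cur, valNumel))
             else curI32(cur)
    out[[length(out) + 1L]] <- bufferEvent(sample, type, value)
  }
  out
}

## -- request encoders (client side) ------------------------------------------

encodePutHeader <- function(header) ftMessage(FT_PUT_HDR, encodeHeaderPayload(header))
encodePutData <- function(values, dataType = "float32")
  ftMessage(FT_PUT_DAT, encodeDataPayload(values, dataType))
encodePutEvent <- function(event) ftMessage(FT_PUT_EVT, encodeEventPayload(event))
encodeGetHeader <- function() ftMessage(FT_GET_HDR)
encodeGetData <- function(begin, end) {
  ## wire selection is inclusive (FieldTrip convention); the in-process API
  ## is half-open, so [begin, end) maps to wire (begin, end - 1)
  ftMessage(FT_GET_DAT, c(wI32(begin), wI32(end - 1)))
}
encodeGetEvents <- function(begin, end)
  ftMessage(FT_GET_EVT, c(wI32(begin), wI32(end - 1)))
encodeWaitData <- function(minTotal, timeoutMs)
  ftMessage(FT_WAIT_DAT, c(wI32(minTotal), wI32(-1L), wI32(timeoutMs)))

decodeMessage <- function(bytes) {
  cur <- rawCursor(bytes)
  version <- curU16(cur)
  if (version != FT_VERSION)
    stopProtocol(sprintf("unsupported protocol version %d", version))
  command <- curU16(cur)
  n <- curI32(cur)
  list(command = command, payload = curTake(cur, n))
}

errPayload <- function(reason) charToRaw(reason)

## -- server-side request handler ---------------------------------------------

#' Serve one framed buffer request
#'
#' Decodes a single wire message, applies it to the buffer, and returns the
#' encoded response message. This is the full server logic; both the TCP
#' server (\code{\link{serveBuffer}}) and the recording replayer
#' (\code{\link{replayRecording}}) funnel through it.
#'
#' @param buffer a \linkS4class{MegBuffer}.
#' @param msg raw vector holding one complete framed request.
#' @return raw vector holding the framed response.
#' @seealso \code{\link{bufferProtocol}}
#' @export
handleBufferRequest <- function(buffer, msg) {
  req <- tryCatch(decodeMessage(msg), megstreamError = function(e) e)
  if (inherits(req, "error"))
    return(ftMessage(FT_GET_ERR, errPayload(paste("malformed:", conditionMessage(req)))))
  cmd <- req$command
  ok <- function(command, payload = raw(0)) ftMessage(command, payload)
  err <- function(command, e) {
    kind <- if (inherits(e, "megstreamNotAvailableError")) "notavail"
            else if (inherits(e, "megstreamEvictedError")) "evicted"
            else "malformed"
    ftMessage(command, errPayload(paste0(kind, ": ", conditionMessage(e))))
  }
  tryCatch({
    if (cmd == FT_PUT_HDR) {
      putHeader(buffer, decodeHeaderPayload(req$payload))
      ok(FT_PUT_OK)
    } else if (cmd == FT_PUT_DAT) {
      putData(buffer, decodeDataPayload(req$payload)$values)
      ok(FT_PUT_OK)
    } else if (cmd == FT_PUT_EVT) {
      for (ev in decodeEventsPayload(req$payload)) putEvent(buffer, ev)
      ok(FT_PUT_OK)
    } else if (cmd == FT_GET_HDR) {
      ok(FT_GET_OK, encodeHeaderPayload(getHeader(buffer)))
    } else if (cmd == FT_GET_DAT) {
      hdr <- getHeader(buffer)
      if (length(req$payload) == 0L) {
        begin <- 0; end <- nSamplesWritten(buffer)
      } else {
        cur <- rawCursor(req$payload)
        begin <- curI32(cur); end <- curI32(cur) + 1  # inclusive -> half-open
      }
      blk <- getData(buffer, begin, end)
      ok(FT_GET_OK, encodeDataPayload(blk@values, hdr@dataType))
    } else if (cmd == FT_GET_EVT) {
      if (length(req$payload) == 0L) {
        begin <- 0; end <- nEventsWritten(buffer)
      } else {
        cur <- rawCursor(req$payload)
        begin <- curI32(cur); end <- curI32(cur) + 1
      }
      evs <- getEvents(buffer, begin, end)
      ok(FT_GET_OK, do.call(c, c(list(raw(0)), lapply(evs, encodeEventPayload))))
    } else if (cmd == FT_WAIT_DAT) {
      cur <- rawCursor(req$payload)
      minTotal <- curI32(cur); curI32(cur); timeoutMs <- curI32(cur)
      n <- waitForSamples(buffer, minTotal, timeoutMs)
      ok(FT_WAIT_OK, c(wI32(n), wI32(nEventsWritten(buffer))))
    } else {
      ftMessage(FT_GET_ERR, errPayload(sprintf("malformed: unknown command 0x%x", cmd)))
    }
  },
  megstreamError = function(e) {
    respCmd <- if (cmd %in% c(FT_PUT_HDR, FT_PUT_DAT, FT_PUT_EVT)) FT_PUT_ERR
               else if (cmd == FT_WAIT_DAT) FT_WAIT_ERR else FT_GET_ERR
    err(respCmd, e)
  })
}

## -- framed socket I/O --------------------------------------------------------

readRawExactly <- function(con, n) {
  out <- raw(0)
  while (length(out) < n) {
    got <- readBin(con, raw(), n - length(out))
    if (length(got) == 0L) {
      if (length(out) == 0L) return(NULL)  # clean EOF between messages
      stopProtocol("connection closed mid-message")
    }
    out <- c(out, got)
  }
  out
}

readFramedMessage <- function(con) {
  head <- readRawExactly(con, 8L)
  if (is.null(head)) return(NULL)
  n <- readBin(head[5:8], integer(), size = 4, endian = "little")
  c(head, if (n > 0) readRawExactly(con, n) else raw(0))
}

#' Serve a buffer over TCP
#'
#' Blocking FieldTrip-protocol server: accepts one client connection at a
#' time on \code{host:port}, serves framed requests against \code{buffer}
#' until the client disconnects, then accepts the next client. Intended for
#' interoperation with third-party FieldTrip clients; in-process use does not
#' need it.
#'
#' @param buffer a \linkS4class{MegBuffer}.
#' @param port TCP port (default 1972, the conventional FieldTrip port).
#' @param host interface to bind.
#' @param maxRequests stop after serving this many requests (default
#'   \code{Inf}; useful for tests and controlled shutdown).
#' @return number of requests served, invisibly.
#' @export
serveBuffer <- function(buffer, port = 1972, host = "127.0.0.1",
                        maxRequests = Inf) {
  served <- 0
  while (served < maxRequests) {
    con <- socketConnection(host = host, port = port, server = TRUE,
                            blocking = TRUE, open = "a+b")
    on.exit(try(close(con), silent = TRUE), add = TRUE)
    repeat {
      msg <- tryCatch(readFramedMessage(con), megstreamError = function(e) NULL)
      if (is.null(msg)) break
      writeBin(handleBufferRequest(buffer, msg), con)
      flush(con)
      served <- served + 1
      if (served >= maxRequests) break
    }
    close(con)
  }
  invisible(served)
}

## -- thin TCP client ----------------------------------------------------------

#' Connect to a served buffer
#'
#' @param host,port endpoint of a \code{\link{serveBuffer}} (or any
#'   FieldTrip-compatible) server.
#' @param timeout socket timeout in seconds.
#' @return a connection object to pass to the \code{remote*} helpers.
#' @rdname remoteBuffer
#' @export
bufferConnect <- function(host = "127.0.0.1", port = 1972, timeout = 10) {
  socketConnection(host = host, port = port, blocking = TRUE, open = "a+b",
                   timeout = timeout)
}

remoteRoundTrip <- function(con, request) {
  writeBin(request, con); flush(con)
  resp <- readFramedMessage(con)
  if (is.null(resp)) stopProtocol("server closed the connection")
  decodeMessage(resp)
}

remoteCheck <- function(resp, okCommand) {
  if (resp$command != okCommand)
    stopProtocol(sprintf("server error: %s",
                         rawToChar(resp$payload)))
  resp
}

#' @param con a connection from \code{bufferConnect}.
#' @param header,values,event,begin,end,minTotal,timeoutMs as in the
#'   corresponding in-process operations.
#' @return decoded response objects mirroring the in-process API.
#' @rdname remoteBuffer
#' @export
remotePutHeader <- function(con, header) {
  remoteCheck(remoteRoundTrip(con, encodePutHeader(header)), FT_PUT_OK)
  invisible(TRUE)
}

#' @rdname remoteBuffer
#' @export
remoteGetHeader <- function(con) {
  resp <- remoteCheck(remoteRoundTrip(con, encodeGetHeader()), FT_GET_OK)
  decodeHeaderPayload(resp$payload)
}

#' @rdname remoteBuffer
#' @param dataType wire value type used to encode the block.
#' @export
remotePutData <- function(con, values, dataType = "float32") {
  remoteCheck(remoteRoundTrip(con, encodePutData(values, dataType)), FT_PUT_OK)
  invisible(TRUE)
}

#' @rdname remoteBuffer
#' @export
remoteGetData <- function(con, begin, end) {
  resp <- remoteCheck(remoteRoundTrip(con, encodeGetData(begin, end)), FT_GET_OK)
  new("SampleBlock", values = decodeDataPayload(resp$payload)$values,
      firstSampleIndex = begin)
}

#' @rdname remoteBuffer
#' @export
remoteWaitForSamples <- function(con, minTotal, timeoutMs) {
  resp <- remoteCheck(remoteRoundTrip(con, encodeWaitData(minTotal, timeoutMs)),
                      FT_WAIT_OK)
  cur <- rawCursor(resp$payload)
  curI32(cur)
}

#' @rdname remoteBuffer
#' @export
remotePutEvent <- function(con, event) {
  remoteCheck(remoteRoundTrip(con, encodePutEvent(event)), FT_PUT_OK)
  invisible(TRUE)
}

#' @rdname remoteBuffer
#' @export
remoteGetEvents <- function(con, begin, end) {
  resp <- remoteCheck(remoteRoundTrip(con, encodeGetEvents(begin, end)), FT_GET_OK)
  decodeEventsPayload(resp$payload)
}

#' Wire protocol dialect
#'
#' This buffer speaks the public FieldTrip buffer protocol: 8-byte request
#' header (\code{uint16} version = 1, \code{uint16} command, \code{uint32}
#' payload byte count), little-endian scalars, sample-major data blocks,
#' standard command codes. Points where the public description is ambiguous
#' are resolved as follows, and constitute this implementation's dialect:
#' \itemize{
#'   \item Error responses (\code{PUT_ERR}/\code{GET_ERR}/\code{WAIT_ERR})
#'     carry a short ASCII reason string prefixed with \code{"malformed:"},
#'     \code{"notavail:"} or \code{"evicted:"}, so clients can distinguish a
#'     bad request from a read past the write pointer or into evicted ring
#'     history. Stock FieldTrip clients that ignore error payloads are
#'     unaffected.
#'   \item \code{GET_DAT}/\code{GET_EVT} selections are inclusive 0-based
#'     index pairs on the wire (FieldTrip convention); the in-process R API
#'     is uniformly half-open \code{[begin, end)}.
#'   \item \code{WAIT_DAT}'s event threshold is accepted but ignored
#'     (\code{-1} recommended); only the sample threshold gates the wait.
#'   \item Supported value types are int16, int32, float32 and float64.
#'   \item The ring retains the most recent 600000 samples by default
#'     (10 min at 1 kHz); the retention horizon is a server-side setting,
#'     not negotiated on the wire.
#' }
#' @name bufferProtocol
NULL
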