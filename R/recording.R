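#' Append-only stream recordings
#'
#' A recording is a file of framed wire messages, byte-identical to what a
#' client would send to a live buffer: one \code{PUT_HDR} message, then
#' \code{PUT_DAT} messages in arrival order, with \code{PUT_EVT} messages
#' appended as events occur. Because the layout mirrors the wire format,
#' \code{\link{replayRecording}} replays a file through the exact same
#' request-handling code that serves live clients, so a recorded session and
#' a live session are processed by one code path.
#'
#' @param path file to create (overwritten).
#' @param header the stream's \linkS4class{BufferHeader}; its
#'   \code{dataType} controls the on-disk value encoding.
#' @return a recording sink handle.
#' @seealso \code{\link{replayRecording}}, \code{\link{bufferProtocol}}
#' @export
recordingSink <- function(path, header) {
  con <- file(path, open = "wb")
  writeBin(encodePutHeader(header), con)
  structure(list(con = con, dataType = header@dataType, path = path),
            class = "megstreamRecordingSink")
}

#' @param sink a sink from \code{recordingSink}.
#' @param values channels x samples matrix chunk.
#' @rdname recordingSink
#' @export
recordChunk <- function(sink, values) {
  writeBin(encodePutData(values, sink$dataType), sink$con)
  invisible(sink)
}

#' @param event a \linkS4class{BufferEvent}.
#' @rdname recordingSink
#' @export
recordEvent <- function(sink, event) {
  writeBin(encodePutEvent(event), sink$con)
  invisible(sink)
}

#' @rdname recordingSink
#' @export
closeRecording <- function(sink) {
  close(sink$con)
  invisible(sink$path)
}

#' Replay a recording into a buffer
#'
#' Reads framed messages from \code{path} and applies each through
#' \code{\link{handleBufferRequest}}, exactly as if a live client had sent
#' them. Stops with an error if the server-side handler rejects a message.
#'
#' @param path a file written by \code{\link{recordingSink}}.
#' @param buffer target \linkS4class{MegBuffer}; a fresh one with
#'   \code{capacity} is created when \code{NULL}.
#' @param capacity ring capacity for the fresh buffer.
#' @return the buffer holding the replayed stream.
#' @export
replayRecording <- function(path, buffer = NULL, capacity = 600000) {
  if (is.null(buffer)) buffer <- megBuffer(capacity = capacity)
  con <- file(path, open = "rb")
  on.exit(close(con))
  repeat {
    msg <- readFramedMessage(con)
    if (is.null(msg)) break
    resp <- decodeMessage(handleBufferRequest(buffer, msg))
    if (resp$command %in% c(FT_PUT_ERR, FT_GET_ERR, FT_WAIT_ERR))
      stopProtocol(sprintf("replay of '%s' rejected: %s",
                           path, rawToChar(resp$payload)))
  }
  buffer
}

#' Read just the header of a recording
#'
#' @param path a recording file.
#' @return the recorded \linkS4class{BufferHeader}.
#' @export
readRecordingHeader <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  msg <- readFramedMessage(con)
  if (is.null(msg)) stopProtocol("empty recording")
  dec <- decodeMessage(msg)
  if (dec$command != FT_PUT_HDR)
    stopProtocol("recording does not start with a header record")
  decodeHeaderPayload(dec$payload)
}
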