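## Classed conditions used across the toolkit. Callers can distinguish a
## malformed request (protocol), a read past the write pointer (notAvailable),
## a read into evicted ring history (evicted), a bad configuration value
## (config) and a physics-domain violation (domain).

msCondition <- function(msg, class, call = sys.call(-1)) {
  structure(
    class = c(class, "megstreamError", "error", "condition"),
    list(message = msg, call = call)
  )
}

stopProtocol <- function(msg) stop(msCondition(msg, "megstreamProtocolError"))
stopNotAvailable <- function(msg) stop(msCondition(msg, "megstreamNotAvailableError"))
stopEvicted <- function(msg) stop(msCondition(msg, "megstreamEvictedError"))
stopConfig <- function(msg) stop(msCondition(msg, "megstreamConfigError"))
stopDomain <- function(msg) stop(msCondition(msg, "megstreamDomainError"))

isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
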