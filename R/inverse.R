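## Noise handling and the precomputed linear inverse: an SSP projector
## estimated from interference-dominated data, a diagonal noise covariance
## from the SSP-cleaned baseline, and the depth-weighted, cortically
## constrained minimum-norm imaging kernel with projection and whitening
## folded in, so the real-time product applies directly to raw sensor data.

#' Estimate a signal-space projection operator
#'
#' U holds the top-k left singular vectors of the channel-mean-removed
#' segment; the projector is P = I - U U'. With k = 0 the projector is the
#' identity.
#'
#' @param segment nChannels x nSamples interference-dominated data.
#' @param k number of interference components (0 <= k < nChannels); the
#'   segment must be longer than k samples.
#' @return an \linkS4class{SspProjector}.
#' @examples
#' seg <- matrix(rnorm(20 * 100), 20, 100)
#' p <- computeSsp(seg, 2)
#' p
#' @export
computeSsp <- function(segment, k) {
  nCh <- nrow(segment)
  if (k >= nCh) stopConfig("k must be smaller than the channel count")
  if (k < 0) stopConfig("k must be >= 0")
  if (ncol(segment) <= k)
    stopConfig("segment must be longer than k samples")
  if (k == 0L) {
    return(new("SspProjector", u = matrix(0, nCh, 0), p = diag(nCh),
               k = 0L))
  }
  centered <- segment - rowMeans(segment)
  u <- svd(centered, nu = k, nv = 0)$u
  new("SspProjector", u = u, p = diag(nCh) - u %*% t(u), k = as.integer(k))
}

#' Apply a projector to sensor data
#'
#' @param projector an \linkS4class{SspProjector}.
#' @param x nChannels x nSamples matrix (or a vector).
#' @return the projected data.
#' @export
applySsp <- function(projector, x) {
  if (is.matrix(x)) projector@p %*% x else as.vector(projector@p %*% x)
}

#' Estimate a diagonal noise covariance
#'
#' Per-channel sample variances of an (SSP-cleaned) baseline segment. A
#' segment of at least one second is required; a constant channel (zero
#' variance) is an error naming the channel.
#'
#' @param segment nChannels x nSamples matrix; row names, when present,
#'   label the channels.
#' @param samplingRate Hz, used to enforce the minimum segment length.
#' @param segmentId free-text provenance tag.
#' @return a \linkS4class{NoiseCovariance}.
#' @export
estimateNoiseCovariance <- function(segment, samplingRate = 1000,
                                    segmentId = "baseline") {
  if (ncol(segment) < samplingRate)
    stopConfig("need at least 1 s of data for the noise covariance")
  v <- apply(segment, 1, stats::var)
  labels <- rownames(segment)
  if (is.null(labels)) labels <- sprintf("CH%03d", seq_len(nrow(segment)))
  if (any(v <= 0)) {
    bad <- labels[which(v <= 0)[1]]
    stopConfig(sprintf("channel %s has zero variance in the baseline segment", bad))
  }
  names(v) <- labels
  new("NoiseCovariance", variances = v, segmentId = segmentId)
}

## cheap content fingerprint used for provenance auditing (not cryptographic)
contentFingerprint <- function(x) {
  v <- as.vector(x)
  sprintf("%dx%d:%.10e:%.10e",
          if (is.matrix(x)) nrow(x) else length(v),
          if (is.matrix(x)) ncol(x) else 1L,
          sum(v), sum(v * seq_along(v) %% 97))
}

#' Compute the WMNE imaging kernel
#'
#' The depth-weighted, cortically constrained minimum-norm inverse with the
#' SSP projector and noise whitening folded in. With per-channel noise SDs
#' sigma, projector P and gain G: the working gain is
#' \eqn{G' = diag(1/\sigma) P G}; diagonal source weights are
#' \eqn{w_j = \|g'_j\|^{-2\gamma}} scaled so that
#' \eqn{trace(G' R G'^T)/n_{channels} = 1}; the regularization is
#' \eqn{\lambda^2 = 1/snr^2}; and the kernel is
#' \eqn{K = R G'^T (G' R G'^T + \lambda^2 I)^{-1}} with rows restricted to
#' the requested ROIs and \eqn{diag(1/\sigma) P} folded into the stored
#' matrix, so it applies to raw (unprojected, unwhitened) sensor vectors.
#' The estimate is linear and stationary: source time series or Fourier
#' coefficients are obtained by a single matrix product.
#'
#' @param gain a \linkS4class{GainMatrix}.
#' @param noise a \linkS4class{NoiseCovariance} (diagonal).
#' @param projector an \linkS4class{SspProjector}, or NULL for identity.
#' @param snr assumed amplitude SNR (default 3, so lambda^2 = 1/9).
#' @param gamma depth-weighting exponent (default 0.5; 0 disables depth
#'   weighting).
#' @param roi ROI labels to retain rows for (default: all ROIs of the gain's
#'   source listing, e.g. the 750 PO + PFC dipoles, giving the default
#'   750 x 306 kernel).
#' @return an \linkS4class{ImagingKernel}.
#' @examples
#' fx <- makeFixture(1)
#' sph <- fitSpheres(fx$scalp, fx$sensors)
#' g <- computeGain(fx$sources, fx$sensors, sph)
#' nc <- new("NoiseCovariance",
#'           variances = stats::setNames(rep(1e-26, 306), channelLabels(g)),
#'           segmentId = "unit")
#' k <- computeWmneKernel(g, nc)
#' dim(values(k))
#' @export
computeWmneKernel <- function(gain, noise, projector = NULL, snr = 3,
                              gamma = 0.5, roi = NULL) {
  G <- values(gain)
  nCh <- nrow(G)
  if (length(noise@variances) != nCh)
    stopConfig("noise covariance dimension must match gain rows")
  if (!is.null(projector) && nrow(projector@p) != nCh)
    stopConfig("projector dimension must match gain rows")
  if (!isScalarNumber(snr) || snr <= 0) stopConfig("snr must be > 0")
  P <- if (is.null(projector)) diag(nCh) else projector@p
  whiten <- 1 / sqrt(noise@variances)
  Gp <- (P %*% G) * whiten                      # diag(1/sigma) P G
  colNorm2 <- colSums(Gp^2)
  if (any(colNorm2 == 0))
    stopConfig("a source column has zero lead field after projection")
  w <- colNorm2^(-gamma)
  tr <- sum(colNorm2 * w)
  w <- w * nCh / tr                             # trace(G' R G'^T)/nCh = 1
  GR <- Gp * rep(w, each = nCh)                 # G' R
  A <- GR %*% t(Gp) + (1 / snr^2) * diag(nCh)   # G' R G'^T + lambda^2 I
  kappa <- kappa(A, exact = FALSE)
  Ainv <- tryCatch(solve(A), error = function(e)
    stopDomain(sprintf(
      "regularized system is numerically singular (condition number %.3e)", kappa)))
  if (!all(is.finite(Ainv)))
    stopDomain(sprintf(
      "regularized system is numerically singular (condition number %.3e)", kappa))
  K <- t(GR) %*% Ainv                           # R G'^T (.)^{-1}, sources x ch
  ## fold whitening + projection so K applies to raw channel vectors
  K <- (K * rep(whiten, each = ncol(G))) %*% P
  roiAll <- roiLabels(gain)
  if (is.null(roi)) roi <- levels(roiAll)
  keep <- which(roiAll %in% roi)
  if (length(keep) == 0L) stopConfig("no sources match the requested ROI(s)")
  new("ImagingKernel",
      values = K[keep, , drop = FALSE],
      lambda2 = 1 / snr^2, gamma = gamma, snr = snr,
      sourceIndex = as.integer(keep),
      roi = factor(as.character(roiAll[keep]), levels = levels(roiAll)),
      gainFingerprint = contentFingerprint(G),
      noiseFingerprint = contentFingerprint(noise@variances))
}

#' @rdname accessors
#' @export
setMethod("values", "ImagingKernel", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("roiLabels", "ImagingKernel", function(x) x@roi)

setMethod("show", "SspProjector", function(object) {
  cat(sprintf("SspProjector: %d channels, k = %d (rank %d)\n",
              nrow(object@p), object@k, nrow(object@p) - object@k))
})

setMethod("show", "NoiseCovariance", function(object) {
  cat(sprintf("NoiseCovariance (diagonal): %d channels, variance range [%.3e, %.3e]\n",
              length(object@variances), min(object@variances),
              max(object@variances)))
})

setMethod("show", "ImagingKernel", function(object) {
  cat(sprintf("ImagingKernel: %d sources x %d channels | lambda2 = %.4g, gamma = %.2g, snr = %g\n",
              nrow(object@values), ncol(object@values), object@lambda2,
              object@gamma, object@snr))
})
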