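## Overlapping-sphere analytic forward model.
##
## Each sensor site gets its own conducting sphere, least-squares fitted to
## the scalp points with Gaussian weights concentrated under that site. The
## magnetic field of a current dipole inside a spherically symmetric
## conductor has the closed-form Sarvas solution, which is independent of the
## conductivity profile and in which radially oriented dipoles are silent.

MU0_OVER_4PI <- 1e-7  # T m / A

#' Fit conducting spheres to scalp points
#'
#' Weighted algebraic least-squares sphere fit: with weights \eqn{w_i} the
#' center c and radius r minimize \eqn{\sum_i w_i (|p_i|^2 - 2 c p_i - k)^2}
#' where \eqn{k = r^2 - |c|^2}, a linear problem. When \code{sensors} is
#' supplied, one sphere is fitted per sensor site with Gaussian weights
#' \code{exp(-d^2 / (2 lengthScale^2))} over the scalp-point distances d to
#' that site; with \code{sensors = NULL} (uniform weights) the fit reduces to
#' the single best-fit sphere, replicated once.
#'
#' @param scalpPoints m x 3 matrix of head-surface points (m >= 10).
#' @param sensors optional \linkS4class{SensorArray}; one sphere per site.
#' @param lengthScale Gaussian weighting length scale in meters.
#' @return a \linkS4class{SphereModel}.
#' @examples
#' pts <- makeFixture(1)$scalp
#' fitSpheres(pts)           # single best-fit sphere
#' @export
fitSpheres <- function(scalpPoints, sensors = NULL, lengthScale = 0.05) {
  scalpPoints <- as.matrix(scalpPoints)
  if (nrow(scalpPoints) < 10)
    stopConfig("need at least 10 scalp points for a sphere fit")
  fitOne <- function(w) {
    A <- cbind(2 * scalpPoints, 1)
    b <- rowSums(scalpPoints^2)
    sw <- sqrt(w / sum(w))
    Aw <- A * sw
    bw <- b * sw
    qrA <- qr(Aw)
    if (qrA$rank < 4L)
      stopDomain("degenerate (coplanar) scalp points: sphere fit is singular")
    beta <- qr.coef(qrA, bw)
    center <- beta[1:3]
    r2 <- beta[4] + sum(center^2)
    if (!is.finite(r2) || r2 <= 0)
      stopDomain("sphere fit produced a non-positive radius")
    radius <- sqrt(r2)
    d <- sqrt(rowSums(sweep(scalpPoints, 2, center)^2)) - radius
    list(center = center, radius = radius,
         residual = sqrt(sum(w * d^2) / sum(w)))
  }
  if (is.null(sensors)) {
    f <- fitOne(rep(1, nrow(scalpPoints)))
    return(new("SphereModel", centers = matrix(f$center, 1, 3),
               radii = f$radius, residuals = f$residual))
  }
  sites <- sensors@sitePositions
  fits <- lapply(seq_len(nrow(sites)), function(i) {
    d2 <- rowSums(sweep(scalpPoints, 2, sites[i, ])^2)
    fitOne(exp(-d2 / (2 * lengthScale^2)))
  })
  new("SphereModel",
      centers = do.call(rbind, lapply(fits, `[[`, "center")),
      radii = vapply(fits, `[[`, numeric(1), "radius"),
      residuals = vapply(fits, `[[`, numeric(1), "residual"))
}

## Vectorized Sarvas solution: field at one exterior point from many dipoles.
## positions, moments: n x 3 (moments in A m); center, fieldPoint: 3-vectors.
## Returns n x 3 matrix of field vectors (T).
sarvasField <- function(positions, moments, center, fieldPoint) {
  r <- fieldPoint - center                      # observation, sphere frame
  R <- sqrt(sum(r^2))
  r0 <- sweep(positions, 2, center)             # dipoles, sphere frame
  r0norm <- sqrt(rowSums(r0^2))
  if (any(r0norm >= R))
    stopDomain("field point must lie strictly outside the sphere containing the dipole")
  a <- -sweep(r0, 2, r)                         # a = r - r0, rowwise
  an <- sqrt(rowSums(a^2))
  ar <- a %*% r                                 # a . r
  r0r <- r0 %*% r                               # r0 . r
  F <- an * (R * an + R^2 - r0r)
  gradCoefR <- an^2 / R + ar / an + 2 * an + 2 * R
  gradCoefR0 <- an + 2 * R + ar / an
  ## grad F = gradCoefR * r - gradCoefR0 * r0   (rowwise)
  gradF <- outer(as.vector(gradCoefR), r) - r0 * as.vector(gradCoefR0)
  Qxr0 <- cbind(moments[, 2] * r0[, 3] - moments[, 3] * r0[, 2],
                moments[, 3] * r0[, 1] - moments[, 1] * r0[, 3],
                moments[, 1] * r0[, 2] - moments[, 2] * r0[, 1])
  Qxr0r <- Qxr0 %*% r
  (MU0_OVER_4PI / as.vector(F)^2) *
    (Qxr0 * as.vector(F) - gradF * as.vector(Qxr0r))
}

#' Magnetic field of a current dipole in a spherical conductor
#'
#' Closed-form (Sarvas) magnetic field of a current dipole inside a
#' spherically symmetric conductor, evaluated at an exterior point. The
#' field is linear in the moment, independent of the conductivity profile,
#' and exactly zero for a radially oriented dipole.
#'
#' @param position dipole position (3-vector, m).
#' @param moment dipole moment (3-vector, A m).
#' @param center sphere center (3-vector, m).
#' @param fieldPoint exterior evaluation point (3-vector, m); must be
#'   strictly farther from \code{center} than the dipole.
#' @return magnetic field 3-vector in tesla.
#' @examples
#' dipoleField(c(0, 0, 0.07), c(1e-8, 0, 0), c(0, 0, 0), c(0, 0.1, 0.06))
#' @export
dipoleField <- function(position, moment, center, fieldPoint) {
  as.vector(sarvasField(matrix(position, 1, 3), matrix(moment, 1, 3),
                        center, fieldPoint))
}

#' Compute the forward gain matrix
#'
#' Entry (i, j) is channel i's reading for a unit moment (1 A m) along
#' dipole j's fixed orientation: the Sarvas field projected on the site
#' normal for magnetometers, and the two-point difference of that projection
#' along the measurement direction, divided by the gradiometer baseline, for
#' planar gradiometers.
#'
#' @param sources a \linkS4class{SourceSpace} (fixed orientations).
#' @param sensors a \linkS4class{SensorArray}.
#' @param spheres a \linkS4class{SphereModel} with one sphere per site, or a
#'   single-sphere model applied to every site.
#' @return a \linkS4class{GainMatrix} (nChannels x nDipoles; T or T/m per A m).
#' @examples
#' fx <- makeFixture(1)
#' sph <- fitSpheres(fx$scalp, fx$sensors)
#' g <- computeGain(fx$sources, fx$sensors, sph)
#' dim(values(g))
#' @export
computeGain <- function(sources, sensors, spheres) {
  nSites <- nrow(sensors@sitePositions)
  singleSphere <- nrow(spheres@centers) == 1L
  if (!singleSphere && nrow(spheres@centers) != nSites)
    stopConfig("sphere model must have 1 sphere or one per sensor site")
  ch <- sensors@channels
  pos <- sources@positions
  ori <- sources@orientations
  G <- matrix(0, nrow(ch), nrow(pos))
  fieldAlongNormal <- function(center, point, normal) {
    ## reading of a point magnetometer at `point` with normal `normal`
    as.vector(sarvasField(pos, ori, center, point) %*% normal)
  }
  for (i in seq_len(nrow(ch))) {
    site <- ch$site[i]
    center <- spheres@centers[if (singleSphere) 1L else site, ]
    p <- sensors@sitePositions[site, ]
    n <- sensors@siteNormals[site, ]
    if (ch$kind[i] == "mag") {
      G[i, ] <- fieldAlongNormal(center, p, n)
    } else {
      u <- c(ch$dirX[i], ch$dirY[i], ch$dirZ[i])
      d <- ch$baseline[i]
      G[i, ] <- (fieldAlongNormal(center, p + (d / 2) * u, n) -
                 fieldAlongNormal(center, p - (d / 2) * u, n)) / d
    }
  }
  new("GainMatrix", values = G, channelLabels = ch$label, roi = sources@roi)
}

## -- accessors / show --------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("values", "GainMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("channelLabels", "GainMatrix", function(x) x@channelLabels)
#' @rdname accessors
#' @export
setMethod("roiLabels", "GainMatrix", function(x) x@roi)
#' @rdname accessors
#' @export
setMethod("nChannels", "SensorArray", function(x) nrow(x@channels))
#' @rdname accessors
#' @export
setMethod("channelLabels", "SensorArray", function(x) x@channels$label)
#' @rdname accessors
#' @export
setMethod("nDipoles", "SourceSpace", function(x) nrow(x@positions))
#' @rdname accessors
#' @export
setMethod("roiLabels", "SourceSpace", function(x) x@roi)

setMethod("show", "SensorArray", function(object) {
  cat(sprintf("SensorArray: %d sites, %d MEG channels (%d mag + %d grad), %d trigger\n",
              nrow(object@sitePositions), nrow(object@channels),
              sum(object@channels$kind == "mag"),
              sum(object@channels$kind == "grad"),
              length(object@triggerLabels)))
})

setMethod("show", "SourceSpace", function(object) {
  tab <- table(object@roi)
  cat(sprintf("SourceSpace: %d dipoles (%s)\n", nrow(object@positions),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "SphereModel", function(object) {
  cat(sprintf("SphereModel: %d sphere(s), radii %.3f-%.3f m, max residual %.2e m\n",
              nrow(object@centers), min(object@radii), max(object@radii),
              max(object@residuals)))
})

setMethod("show", "GainMatrix", function(object) {
  cat(sprintf("GainMatrix: %d channels x %d dipoles\n",
              nrow(object@values), ncol(object@values)))
})
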