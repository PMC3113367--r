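## Synthetic geometry standing in for MRI-derived anatomy and the vendor
## sensor layout: a 102-site helmet cap (1 magnetometer + 2 orthogonal
## planar gradiometers per site), a bumpy quasi-spherical cortical surface
## carrying a parieto-occipital and a prefrontal dipole patch, and scalp
## points for sphere fitting.

withSeed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

unitRows <- function(m) m / sqrt(rowSums(m^2))

## deterministic smooth bump function on the unit sphere (approx in [-1, 1])
makeBumpFun <- function(nTerms = 6) {
  dirs <- unitRows(matrix(rnorm(nTerms * 3), nTerms, 3))
  freq <- runif(nTerms, 3, 6)
  phase <- runif(nTerms, 0, 2 * pi)
  amp <- runif(nTerms, 0.5, 1)
  amp <- amp / sum(amp)
  function(u) {
    proj <- u %*% t(dirs)                      # n x nTerms
    as.vector(cos(sweep(proj, 2, freq, `*`) + rep(phase, each = nrow(u))) %*% amp)
  }
}

## Fibonacci-spiral directions filling a spherical cap of half-angle thetaMax
capDirections <- function(n, thetaMax, centerDir = c(0, 0, 1)) {
  i <- seq_len(n) - 0.5
  u <- 1 - (1 - cos(thetaMax)) * i / n         # cos(theta), 1 .. cos(thetaMax)
  theta <- acos(u)
  phi <- i * pi * (3 - sqrt(5))                # golden angle
  d <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  rotateZTo(d, centerDir)
}

## rotate vectors given in the z-up frame so that z maps onto `target`
rotateZTo <- function(m, target) {
  target <- target / sqrt(sum(target^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * target[3] - z[3] * target[2],
         z[3] * target[1] - z[1] * target[3],
         z[1] * target[2] - z[2] * target[1])
  s <- sqrt(sum(v^2)); cth <- sum(z * target)
  if (s < 1e-12) {
    if (cth > 0) return(m)
    return(m %*% diag(c(1, -1, -1)))           # antipodal: flip about x
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  R <- diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
  m %*% t(R)
}

## tangential directions spanning the plane orthogonal to each unit normal
tangentFrames <- function(normals) {
  ref <- matrix(rep(c(0, 0, 1), nrow(normals)), ncol = 3, byrow = TRUE)
  nearPole <- abs(normals[, 3]) > 0.95
  ref[nearPole, ] <- matrix(rep(c(1, 0, 0), sum(nearPole)), ncol = 3,
                            byrow = TRUE)
  e1 <- cbind(ref[, 2] * normals[, 3] - ref[, 3] * normals[, 2],
              ref[, 3] * normals[, 1] - ref[, 1] * normals[, 3],
              ref[, 1] * normals[, 2] - ref[, 2] * normals[, 1])
  e1 <- unitRows(e1)
  e2 <- cbind(normals[, 2] * e1[, 3] - normals[, 3] * e1[, 2],
              normals[, 3] * e1[, 1] - normals[, 1] * e1[, 3],
              normals[, 1] * e1[, 2] - normals[, 2] * e1[, 1])
  list(e1 = e1, e2 = e2)
}

#' Build the synthetic acquisition fixture
#'
#' Deterministically (given \code{seed}) constructs the geometry the whole
#' toolkit runs on: a 102-site helmet-like sensor cap of radius ~0.12 m
#' (306 MEG channels: 1 magnetometer + 2 orthogonal planar gradiometers per
#' site, 16.8-mm gradiometer baseline) plus 3 integer trigger channels; a
#' bumpy quasi-spherical cortical surface of radius ~0.08 m carrying a
#' posterior parieto-occipital ("PO") patch and an anterior prefrontal
#' ("PFC") patch of fixed-orientation dipoles (750 total by default); and
#' scalp points on a ~0.095 m quasi-sphere for conducting-sphere fitting.
#' Dipole orientations are near-surface-normal but are guaranteed a
#' tangential component of norm >= 0.3 (w.r.t. the head center), since
#' radial dipoles are magnetically silent in a spherical conductor.
#'
#' Head frame: x right, y anterior, z superior, origin at the head center.
#'
#' @param seed integer seed; the same seed reproduces the identical fixture.
#' @param nDipoles total dipole count over both patches (default 750).
#' @param nSites sensor site count (default 102).
#' @param nScalp number of scalp points (default 200).
#' @return a list with elements \code{sensors} (\linkS4class{SensorArray}),
#'   \code{sources} (\linkS4class{SourceSpace}) and \code{scalp}
#'   (matrix of scalp points).
#' @examples
#' fx <- makeFixture(1)
#' fx$sensors
#' fx$sources
#' @export
makeFixture <- function(seed = 1, nDipoles = 750, nSites = 102, nScalp = 200) {
  withSeed(seed, {
    ## -- sensors -------------------------------------------------------------
    siteDirs <- capDirections(nSites, thetaMax = 1.95)   # ~112 degree cap
    sitePositions <- 0.12 * siteDirs
    siteNormals <- siteDirs
    frames <- tangentFrames(siteNormals)
    labels <- as.vector(t(outer(seq_len(nSites),
                                1:3, function(s, k) sprintf("MEG%03d%d", s, k))))
    channels <- data.frame(
      label = labels,
      site = rep(seq_len(nSites), each = 3L),
      kind = rep(c("mag", "grad", "grad"), nSites),
      dirX = as.vector(rbind(siteNormals[, 1], frames$e1[, 1], frames$e2[, 1])),
      dirY = as.vector(rbind(siteNormals[, 2], frames$e1[, 2], frames$e2[, 2])),
      dirZ = as.vector(rbind(siteNormals[, 3], frames$e1[, 3], frames$e2[, 3])),
      baseline = rep(c(0, 0.0168, 0.0168), nSites),
      calibration = rep(c(1e-13, 1e-11, 1e-11), nSites),
      stringsAsFactors = FALSE
    )
    sensors <- new("SensorArray",
                   sitePositions = sitePositions, siteNormals = siteNormals,
                   channels = channels,
                   triggerLabels = c("STI101", "STI102", "STI103"))

    ## -- cortical patches ----------------------------------------------------
    bump <- makeBumpFun()
    nPo <- round(nDipoles * 2 / 3)
    nPfc <- nDipoles - nPo
    poCenter <- c(0, -0.7, 0.55)               # posterior-superior
    pfcCenter <- c(0, 0.85, 0.45)              # anterior-superior
    dirs <- rbind(capDirections(nPo, thetaMax = 0.62, centerDir = poCenter),
                  capDirections(nPfc, thetaMax = 0.50, centerDir = pfcCenter))
    radii <- 0.08 * (1 + 0.04 * bump(dirs))
    positions <- dirs * radii
    ## near-normal orientations with a guaranteed tangential component
    fr <- tangentFrames(dirs)
    ang <- runif(nDipoles, 0, 2 * pi)
    tjit <- fr$e1 * cos(ang) + fr$e2 * sin(ang)
    orientations <- unitRows(dirs + 0.6 * tjit)
    tang <- orientations - dirs * rowSums(orientations * dirs)
    tnorm <- sqrt(rowSums(tang^2))
    low <- tnorm < 0.35
    if (any(low)) {
      tdir <- tang
      tdir[low & tnorm < 1e-9, ] <- tjit[low & tnorm < 1e-9, ]
      tdir <- unitRows(tdir)
      rad <- sign(rowSums(orientations * dirs))
      rad[rad == 0] <- 1
      orientations[low, ] <- sqrt(1 - 0.4^2) * (dirs[low, , drop = FALSE] *
                                                rad[low]) +
                             0.4 * tdir[low, , drop = FALSE]
      orientations <- unitRows(orientations)
    }
    sources <- new("SourceSpace",
                   positions = positions, orientations = orientations,
                   roi = factor(rep(c("PO", "PFC"), c(nPo, nPfc)),
                                levels = c("PO", "PFC")))

    ## -- scalp points --------------------------------------------------------
    scalpBump <- makeBumpFun()
    scalpDirs <- capDirections(nScalp, thetaMax = 2.2)
    scalp <- scalpDirs * (0.095 * (1 + 0.02 * scalpBump(scalpDirs)))

    list(sensors = sensors, sources = sources, scalp = scalp)
  })
}
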