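## Sphere fitting and the spherical-conductor dipole field.

## Independent oracle for the closed-form conductor field, built only from
## potential theory and the primary-current Biot-Savart law: outside the
## conductor B = -mu0 grad U, and along the radial ray through a point the
## scalar potential is U(x) = (1/mu0) * integral_0^inf B_radial(x + s xhat) ds,
## where B_radial is given exactly by the primary dipole term alone (volume
## currents in a spherically symmetric conductor have no radial field).
oracleDipoleField <- function(position, moment, center, fieldPoint,
                              h = 1e-4) {
  U <- function(x) {
    xc <- x - center
    xhat <- xc / sqrt(sum(xc^2))
    r0 <- position - center
    integrand <- function(s) {
      vapply(s, function(si) {
        d <- xc + si * xhat - r0
        cr <- c(moment[2] * d[3] - moment[3] * d[2],
                moment[3] * d[1] - moment[1] * d[3],
                moment[1] * d[2] - moment[2] * d[1])
        sum(cr * xhat) / sum(d^2)^1.5
      }, numeric(1))
    }
    stats::integrate(integrand, 0, Inf, rel.tol = 1e-11)$value / (4 * pi)
  }
  mu0 <- 4 * pi * 1e-7
  -mu0 * vapply(1:3, function(i) {
    e <- c(0, 0, 0); e[i] <- h
    (U(fieldPoint + e) - U(fieldPoint - e)) / (2 * h)
  }, numeric(1))
}

test_that("points sampled exactly on a sphere are recovered to 1e-6", {
  withr::with_seed(2, {
    d <- matrix(rnorm(300), 100, 3)
    d <- d / sqrt(rowSums(d^2))
    centerTrue <- c(0.011, -0.02, 0.033)
    pts <- sweep(0.09 * d, 2, centerTrue, "+")
    fit <- fitSpheres(pts)
    expect_lt(max(abs(fit@centers[1, ] - centerTrue)), 1e-6)
    expect_lt(abs(fit@radii[1] - 0.09), 1e-6)
    expect_lt(fit@residuals[1], 1e-9)
  })
})

test_that("uniform weighting reduces per-site fits to the single best-fit sphere", {
  fx <- defaultFixture()
  single <- fitSpheres(fx$scalp)
  ## a huge length scale makes every per-site weight effectively uniform
  wide <- fitSpheres(fx$scalp, fx$sensors, lengthScale = 1e4)
  expect_equal(wide@centers[1, ], single@centers[1, ], tolerance = 1e-8)
  expect_equal(max(abs(sweep(wide@centers, 2, single@centers[1, ]))), 0,
               tolerance = 1e-8)
  expect_equal(wide@radii, rep(single@radii, length(wide@radii)),
               tolerance = 1e-8)
})

test_that("per-site spheres fit an ellipsoidal head at least as well as one sphere", {
  withr::with_seed(3, {
    d <- matrix(rnorm(600), 200, 3)
    d <- d / sqrt(rowSums(d^2))
    pts <- d %*% diag(c(0.085, 0.095, 0.105))          # ellipsoid
    fx <- defaultFixture()
    single <- fitSpheres(pts)
    persite <- fitSpheres(pts, fx$sensors)
    expect_true(all(persite@residuals <= single@residuals + 1e-12))
    expect_lt(mean(persite@residuals), single@residuals)
  })
})

test_that("degenerate coplanar point sets are rejected", {
  pts <- cbind(matrix(rnorm(60), 30, 2), 0)            # all in z = 0 plane
  expect_error(fitSpheres(pts), class = "megstreamDomainError")
  expect_error(fitSpheres(matrix(rnorm(9), 3, 3)), class = "megstreamConfigError")
})

test_that("radially oriented dipoles are magnetically silent", {
  pos <- c(0.02, -0.03, 0.06)
  center <- c(0, 0.001, -0.002)
  radialMoment <- (pos - center) / sqrt(sum((pos - center)^2)) * 1e-8
  ## the cross product of the numerically constructed radial moment with the
  ## lever arm leaves only rounding residue, ~1e-30 T against ~1e-13 T for a
  ## tangential moment of the same strength
  for (fp in list(c(0, 0.1, 0.08), c(0.11, 0, 0.05), c(-0.07, -0.08, 0.04))) {
    expect_lt(sqrt(sum(dipoleField(pos, radialMoment, center, fp)^2)), 1e-25)
  }
})

test_that("the dipole field is exactly linear in the moment", {
  pos <- c(0, 0.02, 0.07); center <- c(0, 0, 0); fp <- c(0.05, 0.09, 0.08)
  q1 <- c(1e-8, 0, 2e-9); q2 <- c(0, -3e-9, 1e-9)
  b1 <- dipoleField(pos, q1, center, fp)
  b2 <- dipoleField(pos, q2, center, fp)
  b12 <- dipoleField(pos, q1 + q2, center, fp)
  expect_identical(dipoleField(pos, 2 * q1, center, fp), 2 * b1)
  expect_equal(b12, b1 + b2, tolerance = 1e-12)
})

test_that("field points inside the sphere are a domain error", {
  expect_error(dipoleField(c(0, 0, 0.07), c(1e-8, 0, 0), c(0, 0, 0),
                           c(0, 0, 0.05)),
               class = "megstreamDomainError")
})

test_that("the closed form matches the potential-theory quadrature oracle within 1%", {
  configs <- list(
    list(pos = c(0.01, -0.03, 0.06), q = c(1e-8, 2e-9, -4e-9),
         center = c(0, 0, 0), fp = c(0.04, -0.08, 0.09)),
    list(pos = c(-0.02, 0.04, 0.05), q = c(0, -5e-9, 3e-9),
         center = c(0.005, 0, -0.01), fp = c(-0.09, 0.05, 0.07))
  )
  for (cf in configs) {
    closed <- dipoleField(cf$pos, cf$q, cf$center, cf$fp)
    oracle <- oracleDipoleField(cf$pos, cf$q, cf$center, cf$fp)
    expect_lt(sqrt(sum((closed - oracle)^2)) / sqrt(sum(oracle^2)), 0.01)
  }
})

test_that("gain on an all-radial toy source space is numerically zero", {
  fx <- defaultFixture()
  sph <- defaultSpheres()
  ## radial toy sources w.r.t. each site's own sphere center would differ per
  ## channel; use the single best-fit sphere so radial is well defined
  single <- fitSpheres(fx$scalp)
  withr::with_seed(5, {
    d <- matrix(rnorm(60), 20, 3); d <- d / sqrt(rowSums(d^2))
    pos <- sweep(0.06 * d, 2, single@centers[1, ], "+")
    toy <- new("SourceSpace", positions = pos, orientations = d,
               roi = factor(rep("PO", 20), levels = c("PO", "PFC")))
  })
  g <- computeGain(toy, fx$sensors, single)
  magRows <- fx$sensors@channels$kind == "mag"
  expect_lt(max(abs(values(g)[magRows, ])), 1e-20)
})

test_that("permuting dipoles permutes gain columns and subsets concatenate", {
  fx <- defaultFixture()
  sub <- function(idx) new("SourceSpace",
                           positions = fx$sources@positions[idx, , drop = FALSE],
                           orientations = fx$sources@orientations[idx, , drop = FALSE],
                           roi = factor(as.character(fx$sources@roi[idx]),
                                        levels = levels(fx$sources@roi)))
  idxA <- 1:8; idxB <- 101:110
  gAB <- computeGain(sub(c(idxA, idxB)), fx$sensors, defaultSpheres())
  gA <- computeGain(sub(idxA), fx$sensors, defaultSpheres())
  gB <- computeGain(sub(idxB), fx$sensors, defaultSpheres())
  expect_identical(values(gAB), cbind(values(gA), values(gB)))

  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  gP <- computeGain(sub(idxA[perm]), fx$sensors, defaultSpheres())
  expect_identical(values(gP), values(gA)[, perm])
})

test_that("a deeper copy of the same dipole has a smaller gain column norm", {
  fx <- defaultFixture()
  single <- fitSpheres(fx$scalp)
  c0 <- single@centers[1, ]
  i <- 42
  pShallow <- fx$sources@positions[i, ]
  dirIn <- (c0 - pShallow) / sqrt(sum((c0 - pShallow)^2))
  pDeep <- pShallow + 0.02 * dirIn
  toy <- new("SourceSpace",
             positions = rbind(pShallow, pDeep),
             orientations = rbind(fx$sources@orientations[i, ],
                                  fx$sources@orientations[i, ]),
             roi = factor(c("PO", "PO"), levels = c("PO", "PFC")))
  g <- values(computeGain(toy, fx$sensors, single))
  expect_lt(sqrt(sum(g[, 2]^2)), sqrt(sum(g[, 1]^2)))
})

test_that("single-sphere readings are equivariant under global rotation", {
  fx <- defaultFixture()
  single <- fitSpheres(fx$scalp)
  c0 <- single@centers[1, ]
  theta <- 0.7
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  rot <- function(m) sweep(sweep(m, 2, c0) %*% t(R), 2, -c0)
  pos <- c(0.01, -0.04, 0.05); q <- c(2e-9, 1e-8, -3e-9)
  fp <- c(0.05, -0.09, 0.08); n <- c(0.3, -0.8, 0.52); n <- n / sqrt(sum(n^2))
  b0 <- sum(dipoleField(pos, q, c0, fp) * n)
  b1 <- sum(dipoleField(as.vector(rot(matrix(pos, 1))), as.vector(matrix(q, 1) %*% t(R)),
                        c0, as.vector(rot(matrix(fp, 1)))) *
            as.vector(matrix(n, 1) %*% t(R)))
  expect_equal(b0, b1, tolerance = 1e-10)
})
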