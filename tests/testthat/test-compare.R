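## Head positions, RMS% difference and the online/offline comparison on a
## short two-run session (the full-length session is exercised by the
## acceptance checks).

test_that("head positions validate rotations and convert quaternions", {
  expect_error(headPosition(rotation = matrix(1, 3, 3)),
               class = "megstreamConfigError")
  expect_error(headPosition(rotation = diag(c(1, 1, -1))),   # det -1
               class = "megstreamConfigError")
  ## quaternion for 90 degrees about z
  R <- quaternionToRotation(c(cos(pi / 4), 0, 0, sin(pi / 4)))
  expect_equal(R %*% c(1, 0, 0), matrix(c(0, 1, 0)), tolerance = 1e-12)
  hp <- headPosition("r1", translation = c(0, 0, 0.01),
                     rotation = c(cos(pi / 8), 0, 0, sin(pi / 8)))
  expect_equal(det(hp$rotation), 1, tolerance = 1e-12)
})

test_that("applyHeadPosition is a rigid transform of sources and scalp", {
  fx <- defaultFixture()
  hp <- headPosition("r", translation = c(0.002, -0.001, 0.003),
                     rotation = quaternionToRotation(c(cos(0.05), 0, sin(0.05), 0)))
  moved <- applyHeadPosition(fx$sources, fx$scalp, hp)
  ## pairwise distances are preserved
  i <- c(1, 10, 100); j <- c(5, 50, 500)
  d0 <- sqrt(rowSums((fx$sources@positions[i, ] - fx$sources@positions[j, ])^2))
  d1 <- sqrt(rowSums((moved$sources@positions[i, ] - moved$sources@positions[j, ])^2))
  expect_equal(d1, d0, tolerance = 1e-12)
  ## orientations rotate without translating
  expect_equal(sqrt(rowSums(moved$sources@orientations^2)),
               rep(1, 750), tolerance = 1e-12)
  ## identity position is a no-op
  same <- applyHeadPosition(fx$sources, fx$scalp, headPosition("id"))
  expect_equal(same$sources@positions, fx$sources@positions)
  expect_equal(same$scalp, fx$scalp)
})

test_that("rmsPercentDifference has its closed-form values and documented asymmetry", {
  x <- c(1, -2, 3, 0.5)
  expect_equal(rmsPercentDifference(x, x), 0)
  expect_equal(rmsPercentDifference(1.1 * x, x), 10, tolerance = 1e-12)
  ## asymmetry enters only through the normalizer
  a <- c(1, 2, 3); b <- c(2, 2, 2)
  fwd <- rmsPercentDifference(a, b)
  rev <- rmsPercentDifference(b, a)
  expect_equal(fwd / rev, sqrt(sum(a^2)) / sqrt(sum(b^2)), tolerance = 1e-12)
  expect_error(rmsPercentDifference(a, c(0, 0, 0)),
               class = "megstreamConfigError")
  expect_error(rmsPercentDifference(a, b[1:2]), class = "megstreamConfigError")
})

## short session shared by the collapse/displacement checks below
shortSession <- function() memo("shortSession", {
  cfg <- runConfig(seed = 2,
                   schedule = paradigmSchedule(baselineDuration = 5,
                                               nRuns = 2, runDuration = 50))
  runDemo(cfg, outDir = file.path(tempdir(), "megstream-short"),
          sweep = FALSE, quiet = TRUE)
})

test_that("offline equals online when head position and denoising are shared", {
  ses <- shortSession()
  expect_equal(length(ses$onlineSeries), 2)
  for (r in 1:2) {
    on <- megstream:::seriesZ(ses$onlineSeries[[r]])
    off <- megstream:::seriesZ(ses$offlineSeries[[r]])
    expect_equal(length(on), length(off))
    expect_lt(rmsPercentDifference(on, off), 1e-6)
  }
})

test_that("recomputeOffline demands one head position per run", {
  ses <- shortSession()
  expect_error(
    recomputeOffline(ses$recordings, list(headPosition("r1")), ses$fixture,
                     ssp = ses$ssp, noise = ses$noise),
    "missing head position", class = "megstreamConfigError")
})

test_that("per-run offline kernels keep the 750 x 306 shape and a translation breaks identity", {
  ses <- shortSession()
  pos <- list(headPosition("r1", translation = c(0, -0.007, 0.007)),
              headPosition("r2"))
  off <- recomputeOffline(ses$recordings, pos, ses$fixture,
                          ssp = ses$ssp, noise = ses$noise)
  ## run 1 was recomputed at a displaced head: series differ
  rms1 <- rmsPercentDifference(megstream:::seriesZ(ses$onlineSeries[[1]]),
                               megstream:::seriesZ(off[[1]]))
  expect_gt(rms1, 0.1)
  ## run 2 shares geometry: collapse
  rms2 <- rmsPercentDifference(megstream:::seriesZ(ses$onlineSeries[[2]]),
                               megstream:::seriesZ(off[[2]]))
  expect_lt(rms2, 1e-6)
})

test_that("the displacement sweep starts at ~0 and grows with displacement", {
  ses <- shortSession()
  sw <- headMovementSweep(ses$onlineSeries, ses$recordings, ses$fixture,
                          ses$ssp, ses$noise,
                          displacementsMm = c(0, 2.5, 10))
  expect_equal(sw$displacementMm, c(0, 2.5, 10))
  expect_lt(sw$rmsPercent[1], 1)
  expect_gt(sw$rmsPercent[3], sw$rmsPercent[2])     # 10 mm exceeds 2.5 mm
  expect_true(all(diff(sw$rmsPercent) >= 0))
  expect_error(headMovementSweep(ses$onlineSeries, ses$recordings,
                                 ses$fixture, ses$ssp, ses$noise,
                                 displacementsMm = c(2.5, 5)),
               class = "megstreamConfigError")
})
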