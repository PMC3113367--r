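## Source activity generation, sensor synthesis and chunked streaming.

## band power of one series via the smoothed periodogram (Welch-style oracle)
bandPower <- function(x, fs, lo, hi) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), spans = 9,
                          plot = FALSE, detrend = FALSE, taper = 0)
  sum(sp$spec[sp$freq >= lo & sp$freq <= hi])
}

## a schedule with long clean closed/open blocks for spectral estimation
twoStateSchedule <- function() paradigmSchedule(
  baselineDuration = 5, nRuns = 1, runDuration = 120, segmentLength = 60,
  startingState = "closed")

test_that("eyes-closed/open band-power ratio approximates the squared amplitude ratio", {
  fx <- defaultFixture()
  cfg <- simulationConfig(seed = 8, amplitudeRatio = 3)
  S <- simulateSourceActivity(twoStateSchedule(), cfg, fx$sources, run = 1)
  fs <- cfg$samplingRate
  ## trim 1 s around the transition to avoid the envelope ramp
  closed <- S[1, 1000:59000]
  open <- S[1, 61000:119000]
  ratio <- bandPower(closed, fs, 8, 13) / bandPower(open, fs, 8, 13)
  expect_equal(ratio, 9, tolerance = 0.2)

  cfgNull <- simulationConfig(seed = 8, amplitudeRatio = 1)
  S1 <- simulateSourceActivity(twoStateSchedule(), cfgNull, fx$sources, run = 1)
  r1 <- bandPower(S1[1, 1000:59000], fs, 8, 13) /
        bandPower(S1[1, 61000:119000], fs, 8, 13)
  expect_equal(r1, 1, tolerance = 0.3)

  expect_error(simulationConfig(amplitudeRatio = 0.5),
               class = "megstreamConfigError")
})

test_that("PO dipole spectra are concentrated in the 6-15 Hz neighborhood", {
  fx <- defaultFixture()
  cfg <- simulationConfig(seed = 4)
  sch <- paradigmSchedule(baselineDuration = 5, nRuns = 1, runDuration = 60,
                          segmentLength = 20, startingState = "closed")
  S <- simulateSourceActivity(sch, cfg, fx$sources, run = 1)
  poRows <- which(roiLabels(fx$sources) == "PO")
  for (i in poRows[c(1, 100, 400)]) {
    x <- S[i, ]
    X2 <- Mod(stats::fft(x))^2
    f <- (seq_along(x) - 1) * cfg$samplingRate / length(x)
    f <- pmin(f, cfg$samplingRate - f)
    inBand <- sum(X2[f >= 6 & f <= 15])
    expect_gt(inBand / sum(X2), 0.95)
  }
})

test_that("sensor synthesis is linear and zero for silent sources", {
  fx <- defaultFixture()
  g <- defaultGain()
  quiet <- simulationConfig(seed = 5, magNoiseSd = 0, gradNoiseSd = 0,
                            interferenceMagSd = 0, interferenceGradSd = 0)
  S0 <- matrix(0, 750, 500)
  st0 <- synthesizeSensorStream(S0, g, fx$sensors, quiet)
  expect_true(all(st0[1:306, ] == 0))

  withr::with_seed(6, S <- matrix(rnorm(750 * 500) * 1e-9, 750))
  st1 <- synthesizeSensorStream(S, g, fx$sensors, quiet)
  st2 <- synthesizeSensorStream(2 * S, g, fx$sensors, quiet)
  expect_equal(st2[1:306, ], 2 * st1[1:306, ], tolerance = 1e-6)
})

test_that("rank-2 interference produces two dominant covariance eigenvalues", {
  fx <- defaultFixture()
  g <- defaultGain()
  cfg <- simulationConfig(seed = 7, magNoiseSd = 0, gradNoiseSd = 0)
  st <- synthesizeSensorStream(matrix(0, 750, 4000), g, fx$sensors, cfg)
  meg <- st[1:306, ]
  ev <- eigen(stats::cov(t(meg)), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(ev[2] / ev[3], 1e6)          # two dominant directions
})

test_that("cue pulses appear on the first trigger channel with a 100-ms hold", {
  fx <- defaultFixture()
  g <- defaultGain()
  quiet <- simulationConfig(seed = 5, magNoiseSd = 0, gradNoiseSd = 0,
                            interferenceMagSd = 0, interferenceGradSd = 0)
  st <- synthesizeSensorStream(matrix(0, 750, 2000), g, fx$sensors, quiet,
                               cueSamples = c(100, 1200))
  trig <- st[307, ]
  expect_equal(unname(trig[101:200]), rep(2, 100))
  expect_equal(unname(trig[1201:1300]), rep(2, 100))
  expect_true(all(trig[c(1:100, 201:1200, 1301:2000)] == 0))
})

test_that("calibration coefficients round-trip physical values within one step", {
  fx <- defaultFixture()
  withr::with_seed(12, {
    stream <- rbind(matrix(rnorm(306 * 50) *
                             rep(c(1e-12, 1e-10, 1e-10), 102), 306),
                    matrix(0, 3, 50))
  })
  raw <- physicalToRaw(stream, fx$sensors)
  expect_true(all(raw[1:306, ] == round(raw[1:306, ])))
  back <- rawToPhysical(raw, fx$sensors)
  step <- fx$sensors@channels$calibration
  expect_true(all(abs(back[1:306, ] - stream[1:306, ]) <= step / 2 + 1e-30))
})

test_that("streaming chunks have the documented arithmetic and bounds", {
  buf <- megBuffer()
  putHeader(buf, bufferHeader(4, 1000))
  stream <- matrix(rnorm(4 * 1000), 4)

  expect_error(streamToBuffer(buf, stream, chunkSamples = 27),
               "28-sample", class = "megstreamConfigError")
  expect_error(simulationConfig(chunkSamples = 27),
               class = "megstreamConfigError")
  expect_silent(simulationConfig(chunkSamples = 28))

  rep29 <- streamToBuffer(buf, stream, chunkSamples = 29)
  expect_equal(rep29$chunksSent, 35)           # 1000 = 34 * 29 + 14
  expect_equal(rep29$samplesSent, 1000)
  expect_equal(nSamplesWritten(buf), 1000)
  expect_identical(values(getData(buf, 0, 1000)), unname(stream))
  ## last partial chunk has 14 columns
  expect_identical(values(getData(buf, 34 * 29, 1000)),
                   unname(stream[, (34 * 29 + 1):1000]))
})

test_that("realtime pacing yields bit-identical buffer contents to accelerated", {
  stream <- quantizeFloat32(matrix(rnorm(3 * 400), 3))
  bufA <- megBuffer(); putHeader(bufA, bufferHeader(3, 1000))
  bufR <- megBuffer(); putHeader(bufR, bufferHeader(3, 1000))
  streamToBuffer(bufA, stream, 29, pacing = "accelerated")
  t0 <- Sys.time()
  streamToBuffer(bufR, stream, 29, pacing = "realtime", samplingRate = 1000)
  expect_gte(as.numeric(Sys.time() - t0, units = "secs"), 0.35)  # paced
  expect_identical(values(getData(bufA, 0, 400)), values(getData(bufR, 0, 400)))
})

test_that("buffer contents are fully determined by seed, config and schedule", {
  fx <- defaultFixture()
  g <- defaultGain()
  cfg <- simulationConfig(seed = 33)
  sch <- paradigmSchedule(baselineDuration = 2, nRuns = 1, runDuration = 4,
                          segmentLength = 2)
  runOnce <- function() {
    S <- simulateSourceActivity(sch, cfg, fx$sources, run = 1)
    st <- synthesizeSensorStream(S, g, fx$sensors, cfg, seed = cfg$seed + 7)
    buf <- megBuffer()
    putHeader(buf, bufferHeader(nrow(st), cfg$samplingRate))
    streamToBuffer(buf, st, cfg$chunkSamples)
    values(getData(buf, 0, nSamplesWritten(buf)))
  }
  expect_identical(runOnce(), runOnce())
})

test_that("a JSON run configuration round-trips through readRunConfig", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"seed": 5, "snr": 4,
               "sim": {"chunkSamples": 30, "amplitudeRatio": 2.5},
               "schedule": {"nRuns": 2, "runDuration": 60}}', path)
  cfg <- readRunConfig(path)
  expect_equal(cfg$seed, 5)
  expect_equal(cfg$snr, 4)
  expect_equal(cfg$sim$chunkSamples, 30L)
  expect_equal(cfg$sim$seed, 5L)              # top-level seed propagates
  expect_equal(cfg$sim$amplitudeRatio, 2.5)
  expect_equal(length(cfg$schedule$runs), 2)
  expect_equal(cfg$schedule$runs[[1]]$duration, 60)
  expect_equal(cfg$gamma, 0.5)                # defaults fill the rest
})
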