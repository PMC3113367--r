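## SSP, noise covariance and the WMNE imaging kernel.

test_that("SSP with k = 0 is the identity and k >= nChannels is rejected", {
  seg <- matrix(rnorm(12 * 50), 12)
  p0 <- computeSsp(seg, 0)
  expect_identical(p0@p, diag(12))
  expect_error(computeSsp(seg, 12), class = "megstreamConfigError")
  expect_error(computeSsp(matrix(rnorm(12 * 2), 12), 3),
               class = "megstreamConfigError")
})

test_that("SSP removes the interference it was estimated on and is idempotent", {
  fx <- defaultFixture()
  g <- defaultGain()
  cfg <- simulationConfig(seed = 7, magNoiseSd = 0, gradNoiseSd = 0)
  st <- synthesizeSensorStream(matrix(0, 750, 3000), g, fx$sensors, cfg)
  meg <- st[1:306, ]
  proj <- computeSsp(meg, 2)
  resid <- applySsp(proj, meg)
  expect_lt(sqrt(mean(resid^2)), 0.01 * sqrt(mean(meg^2)))
  expect_lt(max(abs(applySsp(proj, resid) - resid)), 1e-10 * max(abs(meg)))
  expect_lt(max(abs(proj@p %*% proj@p - proj@p)), 1e-10)
  expect_equal(sum(diag(proj@p)), 306 - 2, tolerance = 1e-8)  # rank n - k
})

test_that("noise variances are recovered within 10% from 10 s of white noise", {
  withr::with_seed(21, {
    sds <- runif(30, 0.5, 3)
    seg <- matrix(rnorm(30 * 10000), 30) * sds
  })
  nc <- estimateNoiseCovariance(seg, 1000)
  expect_true(all(abs(nc@variances / sds^2 - 1) < 0.1))
})

test_that("degenerate and rescaled baseline segments behave as documented", {
  seg <- matrix(rnorm(5 * 2000), 5)
  rownames(seg) <- sprintf("MEG%03d1", 1:5)
  seg[3, ] <- 1                                     # constant channel
  expect_error(estimateNoiseCovariance(seg, 1000), "MEG0031",
               class = "megstreamConfigError")
  seg[3, ] <- rnorm(2000)
  v1 <- estimateNoiseCovariance(seg, 1000)@variances
  v2 <- estimateNoiseCovariance(2 * seg, 1000)@variances
  expect_equal(v2, 4 * v1, tolerance = 1e-12)
  expect_error(estimateNoiseCovariance(seg[, 1:500], 1000),
               class = "megstreamConfigError")
})

test_that("the default fixture yields a 750 x 306 imaging kernel", {
  k <- computeWmneKernel(defaultGain(), defaultNoiseCov())
  expect_identical(dim(values(k)), c(750L, 306L))
  expect_equal(k@lambda2, 1 / 9)
  ## rows follow the source-space ROI listing
  expect_identical(as.character(k@roi),
                   as.character(roiLabels(defaultFixture()$sources)))
  ## ROI restriction at build time
  kPo <- computeWmneKernel(defaultGain(), defaultNoiseCov(), roi = "PO")
  expect_identical(dim(values(kPo)), c(500L, 306L))
})

test_that("the unregularized, unweighted kernel inverts a square gain", {
  withr::with_seed(31, {
    G <- matrix(rnorm(64), 8, 8) + 5 * diag(8)
    gain <- new("GainMatrix", values = G,
                channelLabels = sprintf("CH%d", 1:8),
                roi = factor(rep("PO", 8), levels = "PO"))
    nc <- new("NoiseCovariance",
              variances = stats::setNames(runif(8, 0.5, 2), sprintf("CH%d", 1:8)),
              segmentId = "toy")
  })
  k <- computeWmneKernel(gain, nc, NULL, snr = 1e6, gamma = 0)
  expect_equal(values(k) %*% G, diag(8), tolerance = 1e-6)
})

test_that("a strong single PO dipole is localized within 1.5 cm", {
  fx <- defaultFixture()
  g <- defaultGain()
  k <- computeWmneKernel(g, defaultNoiseCov())
  sdVec <- ifelse(fx$sensors@channels$kind == "mag", 7e-14, 5.6e-12)
  withr::with_seed(77, {
    for (idx in c(60, 333)) {
      b <- values(g)[, idx, drop = FALSE] %*%
        matrix(sin(2 * pi * 10 * (0:999) / 1000) * 5e-8, 1, 1000)
      b <- b + matrix(rnorm(306 * 1000), 306) * sdVec
      amp <- rowMeans(abs(values(k) %*% b))
      best <- k@sourceIndex[which.max(amp)]
      err <- sqrt(sum((fx$sources@positions[best, ] -
                       fx$sources@positions[idx, ])^2))
      expect_lt(err, 0.015)
    }
  })
})

test_that("the kernel is linear and stationary in the data", {
  k <- computeWmneKernel(defaultGain(), defaultNoiseCov())
  withr::with_seed(15, {
    b1 <- matrix(rnorm(306 * 20), 306)
    b2 <- matrix(rnorm(306 * 20), 306)
  })
  expect_equal(values(k) %*% (b1 + b2),
               values(k) %*% b1 + values(k) %*% b2, tolerance = 1e-12)
})

test_that("the kernel is invariant under rescaling of the noise covariance", {
  g <- defaultGain()
  nc <- defaultNoiseCov()
  ncScaled <- new("NoiseCovariance", variances = 100 * nc@variances,
                  segmentId = nc@segmentId)
  k1 <- computeWmneKernel(g, nc)
  k2 <- computeWmneKernel(g, ncScaled)
  withr::with_seed(16, b <- matrix(rnorm(306 * 5), 306))
  s1 <- values(k1) %*% b
  s2 <- values(k2) %*% b
  expect_lt(max(abs(s1 - s2)) / max(abs(s1)), 1e-8)
})

test_that("depth weighting does not penalize the deep source relative to gamma = 0", {
  fx <- defaultFixture()
  single <- fitSpheres(fx$scalp)
  c0 <- single@centers[1, ]
  i <- 42
  pShallow <- fx$sources@positions[i, ]
  dirIn <- (c0 - pShallow) / sqrt(sum((c0 - pShallow)^2))
  ori <- fx$sources@orientations[i, ]
  toy <- new("SourceSpace",
             positions = rbind(pShallow, pShallow + 0.025 * dirIn),
             orientations = rbind(ori, ori),
             roi = factor(c("PO", "PO"), levels = c("PO", "PFC")))
  g <- computeGain(toy, fx$sensors, single)
  nc <- defaultNoiseCov()
  recovered <- function(gamma) {
    k <- computeWmneKernel(g, nc, NULL, gamma = gamma)
    ## unit-amplitude activity of each dipole in turn
    est <- values(k) %*% values(g)
    c(deep = abs(est[2, 2]), shallow = abs(est[1, 1]))
  }
  r0 <- recovered(0)
  r5 <- recovered(0.5)
  expect_gte(r5["deep"] / r5["shallow"], r0["deep"] / r0["shallow"])
})

test_that("kernels carry provenance fingerprints of their inputs", {
  g <- defaultGain()
  k <- computeWmneKernel(g, defaultNoiseCov())
  expect_identical(k@gainFingerprint,
                   megstream:::contentFingerprint(values(g)))
  k2 <- computeWmneKernel(g, defaultNoiseCov(), snr = 5)
  expect_identical(k@gainFingerprint, k2@gainFingerprint)
  expect_equal(k2@lambda2, 1 / 25)
})
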