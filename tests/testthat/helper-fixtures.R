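## Shared fixtures, memoized so expensive objects are built once per run.

.cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, .cache)) assign(name, force(expr), .cache)
  get(name, .cache)
}

defaultFixture <- function() memo("fixture", makeFixture(1))

defaultSpheres <- function() memo("spheres",
  fitSpheres(defaultFixture()$scalp, defaultFixture()$sensors))

defaultGain <- function() memo("gain",
  computeGain(defaultFixture()$sources, defaultFixture()$sensors,
              defaultSpheres()))

## sensor-noise-only diagonal covariance matching the default array
defaultNoiseCov <- function() memo("noisecov", {
  fx <- defaultFixture()
  sd <- ifelse(fx$sensors@channels$kind == "mag", 7e-14, 5.6e-12)
  seg <- withr::with_seed(41,
    matrix(rnorm(306 * 2000), 306) * sd)
  rownames(seg) <- channelLabels(fx$sensors)
  estimateNoiseCovariance(seg, 1000)
})

## The full accelerated end-to-end demonstration at the study conditions
## (10-s baseline + 3 x 130-s runs at 1 kHz), shared by the acceptance
## checks that assert its outcomes.
fullDemo <- function() memo("fullDemo",
  runDemo(runConfig(seed = 1), outDir = file.path(tempdir(), "megstream-demo"),
          sweep = TRUE, quiet = TRUE))

## small random toy kernel + matching segment maker for pipeline tests
toyKernel <- function(nSrc = 20, nCh = 10, seed = 7) {
  withr::with_seed(seed, {
    new("ImagingKernel",
        values = matrix(rnorm(nSrc * nCh), nSrc, nCh),
        lambda2 = 1 / 9, gamma = 0.5, snr = 3,
        sourceIndex = seq_len(nSrc),
        roi = factor(rep(c("PO", "PFC"), length.out = nSrc),
                     levels = c("PO", "PFC")),
        gainFingerprint = "toy", noiseFingerprint = "toy")
  })
}
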