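test_that("header installation validates and resets the buffer", {
  buf <- megBuffer()
  expect_error(getData(buf, 0, 0), class = "megstreamProtocolError")

  putHeader(buf, bufferHeader(306, 1000))
  hdr <- getHeader(buf)
  expect_identical(nChannels(hdr), 306L)
  expect_equal(samplingRate(hdr), 1000)

  expect_error(bufferHeader(0, 1000), class = "megstreamProtocolError")
  expect_error(bufferHeader(306, -1), class = "megstreamProtocolError")

  putData(buf, matrix(1, 306, 29))
  expect_equal(nSamplesWritten(buf), 29)
  putHeader(buf, bufferHeader(306, 1000))      # reset
  expect_equal(nSamplesWritten(buf), 0)
  expect_equal(nEventsWritten(buf), 0)
  expect_error(getData(buf, 0, 1), class = "megstreamNotAvailableError")
})

test_that("putData enforces shape and accumulates counts", {
  buf <- megBuffer()
  putHeader(buf, bufferHeader(306, 1000))
  putData(buf, matrix(rnorm(306 * 29), 306, 29))
  putData(buf, matrix(rnorm(306 * 29), 306, 29))
  expect_equal(nSamplesWritten(buf), 58)

  putData(buf, matrix(0, 306, 0))              # empty block: ack, no change
  expect_equal(nSamplesWritten(buf), 58)

  expect_error(putData(buf, matrix(0, 309, 29)),
               class = "megstreamProtocolError")
  expect_error(putData(megBuffer(), matrix(0, 306, 29)),
               class = "megstreamProtocolError")
})

test_that("getData returns exactly what was put, bit-identical", {
  buf <- megBuffer()
  putHeader(buf, bufferHeader(5, 1000))
  b1 <- matrix(rnorm(5 * 29), 5, 29)
  b2 <- matrix(rnorm(5 * 29), 5, 29)
  putData(buf, b1); putData(buf, b2)

  expect_identical(values(getData(buf, 29, 58)), b2)
  expect_identical(values(getData(buf, 0, 58)), cbind(b1, b2))
  expect_identical(ncol(values(getData(buf, 7, 7))), 0L)    # empty range
  blk <- getData(buf, 10, 40)                  # straddles the block seam
  expect_identical(blk@values, cbind(b1, b2)[, 11:40])
  expect_equal(firstSampleIndex(blk), 10)

  expect_error(getData(buf, 0, 59), class = "megstreamNotAvailableError")
  expect_error(getData(buf, -1, 10), class = "megstreamProtocolError")
  expect_error(getData(buf, 20, 10), class = "megstreamProtocolError")
})

test_that("round-trip identity holds over arbitrary random put sequences", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      buf <- megBuffer()
      putHeader(buf, bufferHeader(4, 1000))
      blocks <- lapply(seq_len(sample(3:8, 1)), function(i)
        matrix(rnorm(4 * sample(0:60, 1)), nrow = 4))
      for (b in blocks) putData(buf, b)
      full <- do.call(cbind, blocks)
      expect_identical(values(getData(buf, 0, ncol(full))), full)
      ## arbitrary sub-ranges agree with the concatenated input
      if (ncol(full) > 2) {
        a <- sample(0:(ncol(full) - 1), 1)
        b <- sample(a:ncol(full), 1)
        expect_identical(values(getData(buf, a, b)),
                         full[, seq_len(b - a) + a, drop = FALSE])
      }
    }
  })
})

test_that("ring eviction raises a distinct error for aged-out history", {
  buf <- megBuffer(capacity = 100)
  putHeader(buf, bufferHeader(2, 1000))
  for (i in 1:10) putData(buf, matrix(i, 2, 30))
  expect_equal(nSamplesWritten(buf), 300)
  expect_error(getData(buf, 0, 30), class = "megstreamEvictedError")
  ## recent samples still readable
  expect_identical(values(getData(buf, 270, 300)), matrix(10, 2, 30))
})

test_that("events round-trip in insertion order and validate sample bounds", {
  buf <- megBuffer()
  putHeader(buf, bufferHeader(2, 1000))
  putData(buf, matrix(0, 2, 100))
  evs <- list(bufferEvent(3, "trigger", 2L),
              bufferEvent(50, "response", 1L),
              bufferEvent(99, "note", "cue"))
  for (e in evs) putEvent(buf, e)
  got <- getEvents(buf, 0, 3)
  expect_equal(length(got), 3)
  for (i in 1:3) {
    expect_equal(got[[i]]@sample, evs[[i]]@sample)
    expect_identical(got[[i]]@value, evs[[i]]@value)
  }
  expect_identical(getEvents(buf, 1, 1), list())
  expect_error(putEvent(buf, bufferEvent(101, "trigger", 2L)),
               class = "megstreamProtocolError")
  expect_error(getEvents(buf, 0, 4), class = "megstreamProtocolError")
})

test_that("waitForSamples returns immediately when satisfied and at timeout otherwise", {
  buf <- megBuffer()
  putHeader(buf, bufferHeader(2, 1000))
  putData(buf, matrix(0, 2, 29))
  t0 <- Sys.time()
  expect_equal(waitForSamples(buf, 29, 1000), 29)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 0.5)

  t0 <- Sys.time()
  expect_equal(waitForSamples(buf, 1000, 60), 29)      # timeout path
  dt <- as.numeric(Sys.time() - t0, units = "secs")
  expect_gte(dt, 0.05)
  expect_lt(dt, 1)
  expect_error(waitForSamples(buf, 1, -5), class = "megstreamProtocolError")
})
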