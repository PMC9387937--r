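test_that("epoch tiling respects blocks, partial epochs, and segment gaps", {
  env <- EnvelopeSeries(matrix(stats::rnorm(2 * 1200), 2, 1200))
  blocks <- data.frame(start_s = 0, end_s = 300, state = "s")
  es <- epochEnvelope(env, blocks)
  expect_equal(nEpochs(es), 10L)           # 300 / 30

  # 299 s of data -> 9 complete epochs
  env2 <- EnvelopeSeries(matrix(stats::rnorm(2 * 1196), 2, 1196))
  expect_equal(nEpochs(epochEnvelope(env2, blocks)), 9L)

  # a segment boundary mid-block removes epochs spanning the gap: manual
  # tiling oracle says epochs 1-5 fit before bin 620 and epochs from the
  # second segment start at bin 621
  env3 <- EnvelopeSeries(matrix(stats::rnorm(2 * 1200), 2, 1200),
                         segmentBounds = list(c(1L, 620L), c(621L, 1200L)))
  es3 <- epochEnvelope(env3, blocks)
  startBins <- es3@epochStartBin
  expect_false(any(startBins <= 620 & startBins + 119 > 620))

  expect_error(epochEnvelope(env, data.frame(start_s = c(0, 100),
                                             end_s = c(200, 300),
                                             state = c("a", "b"))),
               "non-overlapping")
})

test_that("epoch mean/variance features match closed forms and ground truth", {
  a <- array(3, dim = c(2, 120, 1))
  es <- new("EpochSet", epochs = a, labels = "s", epochStartBin = 1L,
            epochStartS = 0, binMs = 250, channelIds = c("a", "b"),
            subjectTag = "")
  mv <- epochMeanVar(es)
  expect_equal(as.numeric(mv), c(3, 3, 0, 0))

  a2 <- array(rep(c(1, -1), 120), dim = c(1, 120, 1))
  es2 <- new("EpochSet", epochs = a2, labels = "s", epochStartBin = 1L,
             epochStartS = 0, binMs = 250, channelIds = "a", subjectTag = "")
  mv2 <- epochMeanVar(es2)
  expect_equal(unname(mv2[1, 1]), 0)
  expect_equal(unname(mv2[1, 2]), 120 / 119)       # sample variance of +/-1

  # planted mean shift appears as the feature-wise class-mean difference
  q <- 4; delta <- 1.3
  sp <- list(
    lo = StateSpec("lo", rep(2, q), rep(1, q), matrix(1e-8, q, 1), 500, 1),
    hi = StateSpec("hi", rep(2 + delta, q), rep(1, q), matrix(1e-8, q, 1),
                   500, 1))
  gen <- generateEnvelopeDataset(sp, makeSchedule(c("lo", "hi"), 4), seed = 6)
  es3 <- epochEnvelope(gen$env, gen$labels)
  mv3 <- epochMeanVar(es3)
  dMean <- colMeans(mv3[epochLabels(es3) == "hi", 1:q]) -
    colMeans(mv3[epochLabels(es3) == "lo", 1:q])
  expect_equal(unname(dMean), rep(delta, q), tolerance = 0.1)
})

test_that("epoch covariance features capture planted correlation structure", {
  # two perfectly correlated channels
  z <- stats::rnorm(120)
  a <- array(rbind(2 * z, 3 * z), dim = c(2, 120, 1))
  es <- new("EpochSet", epochs = a, labels = "s", epochStartBin = 1L,
            epochStartS = 0, binMs = 250, channelIds = c("a", "b"),
            subjectTag = "")
  cv <- epochCovariance(es)
  expect_equal(cv[1, 2, 1], sqrt(cv[1, 1, 1] * cv[2, 2, 1]),
               tolerance = 1e-10)

  # symmetry + PSD
  expect_equal(cv[, , 1], t(cv[, , 1]))
  expect_gte(min(eigen(cv[, , 1], symmetric = TRUE,
                       only.values = TRUE)$values), -1e-10)

  # sign-flip construct: class-mean covariances differ in off-diagonal sign,
  # and diagonals are ~1 on z-scored input
  gen <- generateEnvelopeDataset(pureCovSpecs(q = 4),
                                 makeSchedule(c("A", "B"), 4), seed = 7)
  envZ <- zscoreSegments(gen$env, blocks = gen$labels)
  esZ <- epochEnvelope(envZ, gen$labels)
  cvZ <- epochCovariance(esZ)
  labs <- epochLabels(esZ)
  mA <- apply(cvZ[, , labs == "A"], c(1, 2), mean)
  mB <- apply(cvZ[, , labs == "B"], c(1, 2), mean)
  expect_gt(mA[1, 2], 0.2)
  expect_lt(mB[1, 2], -0.2)
  expect_equal(diag(mA), rep(1, 4), tolerance = 0.15)

  expect_warning(
    epochCovariance(new("EpochSet",
                        epochs = array(stats::rnorm(5 * 3 * 2),
                                       dim = c(5, 3, 2)),
                        labels = c("a", "a"), epochStartBin = c(1L, 4L),
                        epochStartS = c(0, 1), binMs = 250,
                        channelIds = sprintf("c%d", 1:5), subjectTag = "")),
    "rank-deficient")
})

test_that("slow/fast band split separates timescales around 0.333 Hz", {
  tS <- (0:4799) * 0.25
  blocks <- data.frame(start_s = 0, end_s = 1200, state = "s")

  mk <- function(f, a = 1) EnvelopeSeries(matrix(a * sin(2 * pi * f * tS),
                                                 2, 4800, byrow = TRUE))
  bs01 <- bandsplitEnvelope(mk(0.1), blocks)
  expect_gt(mean(bs01$slow), 5 * mean(bs01$fast))

  bs1 <- bandsplitEnvelope(mk(1), blocks)
  expect_gt(mean(bs1$fast), 5 * mean(bs1$slow))

  # amplitude-a tone below cutoff: slow feature ~ a (analytic magnitude)
  a <- 0.7
  bs005 <- bandsplitEnvelope(mk(0.05, a), blocks)
  expect_equal(mean(bs005$slow), a, tolerance = 0.05)
})

test_that("Welch PSD is calibrated, peaks at tones, and is flat for white noise", {
  set.seed(8)
  env <- EnvelopeSeries(matrix(stats::rnorm(1 * 2400), 1, 2400))
  blocks <- data.frame(start_s = 0, end_s = 600, state = "s")
  es <- epochEnvelope(env, blocks)
  psd <- welchPSD(es)
  # total power ~ variance (Parseval, within 10%)
  df <- psd$freq[2] - psd$freq[1]
  totP <- sum(psd$power) * df
  expect_lt(abs(totP - stats::var(env@values[1, ])) /
              stats::var(env@values[1, ]), 0.1)
  # flat within 3 SE of the mean level for most bins
  dev <- abs(psd$power - mean(psd$power)) / psd$se
  expect_lt(stats::median(dev, na.rm = TRUE), 3)

  # 0.5 Hz tone: global maximum at the nearest frequency bin
  tS <- (0:2399) * 0.25
  envT <- EnvelopeSeries(matrix(sin(2 * pi * 0.5 * tS), 1, 2400))
  psdT <- welchPSD(epochEnvelope(envT, blocks))
  expect_lt(abs(psdT$freq[which.max(psdT$power)] - 0.5), 0.02)

  # single 30-s epoch -> no standard error
  one <- epochEnvelope(EnvelopeSeries(matrix(stats::rnorm(120), 1, 120)),
                       data.frame(start_s = 0, end_s = 30, state = "s"))
  expect_true(all(is.na(welchPSD(one)$se)))
})
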