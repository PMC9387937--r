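test_that("factor analysis recovers a planted loading subspace", {
  set.seed(1)
  q <- 10; p <- 2; n <- 6000
  C <- matrix(stats::rnorm(q * p), q, p)
  z <- matrix(stats::rnorm(p * n), p, n)
  Y <- C %*% z + matrix(stats::rnorm(q * n, sd = 0.5), q, n)
  a <- array(Y, dim = c(q, n / 10, 10))
  fit <- faFit(a, p, maxIter = 500)
  expect_lt(subspaceAngleDeg(C, loadingMatrix(fit)), 10)
  expect_false(is.unsorted(fitLog(fit)))
})

test_that("zero-factor FA is pure diagonal noise and smoothing at 0 is identity", {
  set.seed(2)
  a <- array(stats::rnorm(4 * 30 * 5, sd = 2), dim = c(4, 30, 5))
  f0 <- faFit(a, 0)
  Y <- a; dim(Y) <- c(4, 150)
  expect_equal(unname(noiseVariances(f0)),
               unname(apply(Y, 1, stats::var) * 149 / 150),
               tolerance = 1e-8)
  expect_equal(ncol(loadingMatrix(f0)), 0L)

  f1 <- faFit(a, 2, preSmoothMs = 0, maxIter = 50)
  f2 <- faFit(a, 2, maxIter = 50)
  expect_equal(loadingMatrix(f1), loadingMatrix(f2))
})

test_that("GPFA EM increases the likelihood and recovers scaled-down truth", {
  set.seed(3)
  q <- 8; tausTrue <- c(500, 4000)
  C <- matrix(stats::rnorm(q * 2, sd = 0.8), q, 2)
  es <- makeGpfaEpochSet(q = q, tausMs = tausTrue, Tn = 60, E = 20,
                         seed = 3, C = C)
  fit <- suppressWarnings(gpfaFitEM(epochArray(es), 2, maxIter = 120,
                                    tol = 1e-6, seed = 1))
  lg <- fitLog(fit)
  expect_true(all(diff(lg) > -1e-6 * abs(lg[-1])))
  tf <- sort(timescales(fit))
  expect_true(all(abs(tf - tausTrue) / tausTrue < 0.5))
  expect_lt(subspaceAngleDeg(C, loadingMatrix(fit)), 15)
})

test_that("with white latents GPFA collapses to the FA likelihood", {
  set.seed(4)
  es <- makeGpfaEpochSet(q = 6, tausMs = c(1, 1), Tn = 40, E = 15, seed = 4)
  a <- epochArray(es)
  fFA <- faFit(a, 2, maxIter = 400, tol = 1e-8)
  fGP <- suppressWarnings(gpfaFitEM(a, 2, maxIter = 150, tol = 1e-8,
                                    seed = 1))
  llFA <- max(fitLog(fFA))
  llGP <- max(fitLog(fGP))
  expect_lt(abs(llGP - llFA) / abs(llFA), 0.01)
})

test_that("GPFA posterior equals brute-force joint-Gaussian conditioning", {
  set.seed(5)
  for (case in list(c(p = 1, Tn = 3, q = 4), c(p = 3, Tn = 12, q = 6),
                    c(p = 5, Tn = 12, q = 9))) {
    p <- case["p"]; Tn <- case["Tn"]; q <- case["q"]
    C <- matrix(stats::rnorm(q * p), q, p)
    d <- stats::rnorm(q)
    R <- stats::runif(q, 0.3, 1.5)
    taus <- stats::runif(p, 300, 5000)
    params <- new(Class = "GPFAParams", C = C, d = d, R = R, tausMs = taus,
                  sigmaNSq = 1e-3, binMs = 250, fitLog = numeric(0),
                  converged = TRUE)
    y <- matrix(stats::rnorm(q * Tn), q, Tn)
    m <- gpfaPosterior(params, y)

    # oracle: explicit joint covariance of (x, y), time-major latent order
    K <- matrix(0, p * Tn, p * Tn)
    for (i in seq_len(p)) {
      idx <- seq(i, by = p, length.out = Tn)
      K[idx, idx] <- gammastate:::gpKernel(taus[i], Tn, 250, 1e-3)
    }
    Ct <- kronecker(diag(Tn), C)
    SigY <- Ct %*% K %*% t(Ct) + diag(rep(R, Tn))
    mOracle <- K %*% t(Ct) %*% solve(SigY, as.vector(y - d))
    expect_lt(max(abs(as.vector(m) - mOracle)), 1e-8)
  }
})

test_that("GPFA posterior limits: uninformative data and noiseless recovery", {
  set.seed(6)
  q <- 6; p <- 2; Tn <- 10
  C <- qr.Q(qr(matrix(stats::rnorm(q * p), q, p)))   # orthonormal columns
  d <- stats::rnorm(q)
  mkP <- function(R, taus) new(Class = "GPFAParams", C = C, d = d,
                               R = rep(R, q), tausMs = taus,
                               sigmaNSq = 1e-3, binMs = 250,
                               fitLog = numeric(0), converged = TRUE)
  y <- matrix(stats::rnorm(q * Tn), q, Tn)
  # R -> infinity: posterior collapses to the prior mean 0
  expect_lt(max(abs(gpfaPosterior(mkP(1e12, c(500, 500)), y))), 1e-6)

  # noiseless y = C x + d, huge tau handled by pseudo-inverse oracle
  xTrue <- sampleGPLatents(c(3000, 3000), Tn, seed = 7)
  yc <- C %*% xTrue + d
  post <- gpfaPosterior(mkP(1e-8, c(3000, 3000)), yc)
  xPinv <- crossprod(C, yc - d)                       # C orthonormal
  expect_lt(max(abs(post - xPinv)), 1e-3)
})

test_that("orthonormalization satisfies its algebraic identities", {
  set.seed(8)
  Cgen <- cbind(stats::rnorm(8, sd = 1.6), stats::rnorm(8, sd = 0.5))
  es <- makeGpfaEpochSet(q = 8, tausMs = c(800, 5000), Tn = 30, E = 10,
                         seed = 8, C = Cgen)
  fit <- suppressWarnings(gpfaFitEM(epochArray(es), 2, maxIter = 60,
                                    tol = 1e-5, seed = 1))
  tr <- inferLatents(fit, es)
  ot <- orthonormalize(fit, tr)
  # U has orthonormal columns, D ordered decreasing
  expect_lt(max(abs(crossprod(ot@U) - diag(2))), 1e-10)
  expect_false(is.unsorted(rev(ot@Ddiag)))
  # reconstruction identity U x~ = C x per bin
  for (e in c(1, 5))
    expect_lt(max(abs(loadingMatrix(fit) %*% latentPaths(tr)[, , e] -
                        ot@U %*% latentPaths(ot)[, , e])), 1e-10)
  # variance of orthonormalized rows decreases with singular-value order
  v <- apply(latentPaths(ot), 1, function(m) stats::var(as.vector(m)))
  expect_false(is.unsorted(rev(v)))

  # already-orthonormal loading with identity D: x~ = x up to sign
  Cq <- qr.Q(qr(matrix(stats::rnorm(8 * 2), 8, 2)))
  pq <- new(Class = "GPFAParams", C = Cq, d = rep(0, 8), R = rep(1, 8),
            tausMs = c(500, 500), sigmaNSq = 1e-3, binMs = 250,
            fitLog = numeric(0), converged = TRUE)
  trq <- inferLatents(pq, es)
  otq <- orthonormalize(pq, trq)
  expect_equal(abs(latentPaths(otq)), abs(latentPaths(trq)),
               tolerance = 1e-8)
})

test_that("leave-one-channel-out error vanishes on noiseless rank-p data", {
  set.seed(9)
  q <- 6; p <- 2; Tn <- 20; E <- 4
  C <- matrix(stats::rnorm(q * p), q, p)
  a <- array(0, dim = c(q, Tn, E))
  for (e in 1:E) a[, , e] <- C %*% sampleGPLatents(c(2000, 2000), Tn)
  params <- new(Class = "GPFAParams", C = C, d = rep(0, q), R = rep(1e-9, q),
                tausMs = c(2000, 2000), sigmaNSq = 1e-3, binMs = 250,
                fitLog = numeric(0), converged = TRUE)
  r <- looRMSE(params, a, rep("A", E))
  expect_lt(r$total, 1e-3)
})

test_that("per-fold latent decoding localizes planted discriminative factors", {
  # only the slow factor separates classes: its loading flips sign by class
  set.seed(10)
  q <- 8
  gen <- generateEnvelopeDataset(pureCovSpecs(q = q, tauMs = 4000),
                                 makeSchedule(c("A", "B"), 4,
                                              blockLenS = 150),
                                 seed = 10)
  envZ <- zscoreSegments(gen$env, blocks = gen$labels)
  es <- epochEnvelope(envZ, gen$labels)
  plan <- makeCVPlan(es, k = 4)
  folds <- suppressWarnings(gpfaFoldLatents(es, plan = plan, p = 2,
                                            seed = 11, maxIter = 40,
                                            tol = 1e-4))
  slow <- factorDecodingCurve(folds, "slow_first")
  fast <- factorDecodingCurve(folds, "fast_first")
  # both orders use the identical feature set at m = p
  expect_equal(slow$accuracy[2], fast$accuracy[2], tolerance = 1e-12)
  single <- singleFactorDecoding(folds)
  expect_equal(nrow(single), 2L)
  expect_false(is.unsorted(rev(single$meanTauMs)))
})
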