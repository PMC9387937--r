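# Gaussian process factor analysis: EM fitting with per-factor timescale
# estimation, exact posterior latent inference, orthonormalization, and
# leave-one-channel-out prediction error.

# Per-factor squared-exponential kernel pieces at epoch length Tn.
gpKernelFactor <- function(tauMs, Tn, binMs, sigmaNSq) {
  L <- cholSafe(gpKernel(tauMs, Tn, binMs, sigmaNSq))
  list(Kinv = chol2inv(L), logdet = 2 * sum(log(diag(L))))
}

# Posterior operator for one parameter set at epoch length Tn. Latents are
# vectorized time-major (factor index fastest), so the GP prior precision is
# block-sparse per factor and the observation precision is block-diagonal
# per time point.
gpfaOperator <- function(C, R, tausMs, sigmaNSq, Tn, binMs) {
  p <- ncol(C)
  pT <- p * Tn
  Kinv <- matrix(0, pT, pT)
  logdetK <- 0
  cache <- list()
  for (i in seq_len(p)) {
    key <- sprintf("%.12g", tausMs[i])
    if (is.null(cache[[key]]))
      cache[[key]] <- gpKernelFactor(tausMs[i], Tn, binMs, sigmaNSq)
    idx <- seq(i, by = p, length.out = Tn)
    Kinv[idx, idx] <- cache[[key]]$Kinv
    logdetK <- logdetK + cache[[key]]$logdet
  }
  A <- crossprod(C, C / R)
  M <- Kinv
  for (t in seq_len(Tn)) {
    idx <- (t - 1) * p + seq_len(p)
    M[idx, idx] <- M[idx, idx] + A
  }
  Lm <- cholSafe(M)
  list(p = p, Tn = Tn, SigmaX = chol2inv(Lm), logdetK = logdetK,
       logdetM = 2 * sum(log(diag(Lm))))
}

# Posterior mean (p x Tn) and the information vector b for one epoch.
gpfaPosteriorMean <- function(op, C, R, d, y) {
  u <- y - d
  b <- as.vector(crossprod(C, u / R))
  m <- op$SigmaX %*% b
  list(mean = matrix(m, op$p, op$Tn), b = b, m = as.vector(m), u = u)
}

#' Fit Gaussian process factor analysis by EM
#'
#' Observation model `y_t | x_t ~ N(C x_t + d, R)` with diagonal `R`; each
#' latent factor is an independent zero-mean Gaussian process over the epoch
#' with unit-variance squared-exponential kernel
#' `(1 - sigmaNSq) exp(-dt^2 / (2 tau_i^2)) + sigmaNSq 1[dt = 0]`.
#' The E-step computes the exact joint-Gaussian posterior of all latents in
#' an epoch; the M-step updates `C`, `d`, `R` in closed form and each
#' `tau_i` by 1-D maximization of the expected log-likelihood in log-tau
#' space (`sigmaNSq` held fixed). `C`, `d`, `R` are initialized from a
#' factor-analysis fit and the timescales from a cycling ladder
#' 500, 1000, 2000, ... ms.
#'
#' @param epochs an [EpochSet-class] or `[q, T, E]` array.
#' @param p latent dimensionality (`1 <= p < q`).
#' @param maxIter maximum EM iterations (default 500).
#' @param tol relative log-likelihood gain for convergence (default 1e-6).
#' @param seed integer seed (propagated to the FA initializer).
#' @param sigmaNSq GP kernel noise floor (default 1e-3).
#' @param binMs bin width (ms) when `epochs` is a bare array.
#' @param tauInitMs optional explicit initial timescales.
#' @return A [GPFAParams-class] with a non-decreasing `fitLog`.
#' @export
gpfaFitEM <- function(epochs, p, maxIter = 500, tol = 1e-6, seed = 1,
                      sigmaNSq = 1e-3, binMs = 250, tauInitMs = NULL) {
  if (is(epochs, "EpochSet")) binMs <- epochs@binMs
  a <- asEpochArray(epochs)
  dm <- dim(a)
  q <- dm[1]; Tn <- dm[2]; E <- dm[3]
  if (p < 1 || p >= q) stop("need 1 <= p < q")
  if (E * Tn <= q) stop("need more bins than channels")

  fa <- faFit(a, p, maxIter = min(200, maxIter), tol = tol, seed = seed,
              binMs = binMs)
  C <- fa@C; d <- fa@d; R <- fa@R
  taus <- if (!is.null(tauInitMs)) rep(tauInitMs, length.out = p)
          else 500 * 2^((seq_len(p) - 1) %% 6)
  tauLo <- log(binMs / 2); tauHi <- log(100 * Tn * binMs)

  Y <- flattenEpochs(a)
  Syy <- tcrossprod(Y)
  sumY <- rowSums(Y)
  N <- Tn * E
  varY <- pmax(apply(Y, 1, stats::var), 1e-12)

  fitLogV <- numeric(0); converged <- FALSE
  for (it in seq_len(maxIter)) {
    op <- gpfaOperator(C, R, taus, sigmaNSq, Tn, binMs)
    # E-step: posterior means for all epochs + log-likelihood
    Mflat <- matrix(0, p, N)       # means, epoch-major then time
    ll <- 0
    quadConst <- q * Tn * log(2 * pi) + Tn * sum(log(R)) +
      op$logdetK + op$logdetM
    for (e in seq_len(E)) {
      ps <- gpfaPosteriorMean(op, C, R, d, a[, , e])
      Mflat[, (e - 1) * Tn + seq_len(Tn)] <- ps$mean
      ll <- ll - 0.5 * (quadConst + sum(ps$u^2 / R) - sum(ps$m * ps$b))
    }
    fitLogV <- c(fitLogV, ll)
    if (it > 1 && (ll - fitLogV[it - 1]) < tol * abs(fitLogV[it - 1])) {
      converged <- TRUE
      break
    }
    # posterior covariance block sums
    sumDiag <- matrix(0, p, p)
    for (t in seq_len(Tn)) {
      idx <- (t - 1) * p + seq_len(p)
      sumDiag <- sumDiag + op$SigmaX[idx, idx]
    }
    Sxx <- E * sumDiag + tcrossprod(Mflat)
    sumM <- rowSums(Mflat)
    A1 <- cbind(Y %*% t(Mflat), sumY)
    A2 <- rbind(cbind(Sxx, sumM), c(sumM, N))
    Cd <- A1 %*% solve(A2)
    C <- Cd[, seq_len(p), drop = FALSE]
    d <- Cd[, p + 1]
    R <- pmax(diag(Syy - Cd %*% t(A1)) / N, 1e-8 * varY)
    # timescale update: 1-D expected log-likelihood maximization per factor
    for (i in seq_len(p)) {
      idx <- seq(i, by = p, length.out = Tn)
      mi <- matrix(Mflat[i, ], Tn, E)
      Si <- E * op$SigmaX[idx, idx] + tcrossprod(mi)
      negQ <- function(lt) {
        f <- gpKernelFactor(exp(lt), Tn, binMs, sigmaNSq)
        E * f$logdet + sum(f$Kinv * Si)
      }
      opt <- stats::optimize(negQ, c(tauLo, tauHi), tol = 1e-3)
      if (opt$objective < negQ(log(taus[i])) - 1e-12)
        taus[i] <- exp(opt$minimum)
    }
  }
  if (!converged) warning("GPFA EM did not converge within maxIter")
  new(Class = "GPFAParams", C = C, d = d, R = R, tausMs = taus,
      sigmaNSq = sigmaNSq, binMs = binMs, fitLog = fitLogV,
      converged = converged)
}

#' Posterior latent trajectory of one epoch
#'
#' Exact conditional mean `E[x | y]` of the `pT`-dimensional latent Gaussian
#' given the epoch, under the fitted model.
#'
#' @param params a fitted [GPFAParams-class] (GPFA or FA).
#' @param epoch numeric `q x T` matrix.
#' @return numeric `p x T` matrix of posterior means.
#' @export
gpfaPosterior <- function(params, epoch) {
  Tn <- ncol(epoch)
  if (length(params@tausMs)) {
    op <- gpfaOperator(params@C, params@R, params@tausMs, params@sigmaNSq,
                       Tn, params@binMs)
    gpfaPosteriorMean(op, params@C, params@R, params@d, epoch)$mean
  } else {
    faPosteriorMeans(params@C, params@R, params@d, epoch)
  }
}

# FA conditioning: time points independent.
faPosteriorMeans <- function(C, R, d, y) {
  p <- ncol(C)
  if (p == 0) return(matrix(0, 0, ncol(y)))
  G <- solve(diag(p) + crossprod(C, C / R))
  G %*% crossprod(C, (y - d) / R)
}

#' Infer latent trajectories for a set of epochs
#'
#' @param params a fitted [GPFAParams-class].
#' @param epochs an [EpochSet-class] or `[q, T, E]` array.
#' @return A [LatentTrajectories-class] (raw, not orthonormalized).
#' @export
inferLatents <- function(params, epochs) {
  a <- asEpochArray(epochs)
  dm <- dim(a)
  p <- ncol(params@C)
  paths <- array(0, dim = c(p, dm[2], dm[3]))
  if (length(params@tausMs)) {
    op <- gpfaOperator(params@C, params@R, params@tausMs, params@sigmaNSq,
                       dm[2], params@binMs)
    for (e in seq_len(dm[3]))
      paths[, , e] <- gpfaPosteriorMean(op, params@C, params@R, params@d,
                                        a[, , e])$mean
  } else {
    for (e in seq_len(dm[3]))
      paths[, , e] <- faPosteriorMeans(params@C, params@R, params@d, a[, , e])
  }
  new("LatentTrajectories", paths = paths, ortho = FALSE,
      U = matrix(0, 0, 0), Ddiag = numeric(0), tausMs = params@tausMs,
      binMs = params@binMs)
}

#' Orthonormalize latent trajectories through the SVD of the loading
#'
#' Decomposes `C = U D V'` and maps trajectories to `x~ = D V' x`, so
#' `U x~ = C x` exactly and the rows of `x~` are ordered by the covariance
#' they explain (singular values descending). Sign convention: the
#' largest-magnitude entry of each column of `U` is positive. Zero singular
#' directions of a rank-deficient `C` are dropped with a warning.
#'
#' @param params the [GPFAParams-class] the trajectories were inferred under.
#' @param trajs a [LatentTrajectories-class] from [inferLatents()].
#' @return A [LatentTrajectories-class] with `ortho = TRUE`.
#' @export
orthonormalize <- function(params, trajs) {
  a <- if (is(trajs, "LatentTrajectories")) trajs@paths else trajs
  sv <- svd(params@C)
  keep <- sv$d > max(sv$d) * 1e-12
  if (!all(keep)) warning("rank-deficient loading: zero singular directions dropped")
  U <- sv$u[, keep, drop = FALSE]
  D <- sv$d[keep]
  V <- sv$v[, keep, drop = FALSE]
  flip <- vapply(seq_len(ncol(U)), function(k) {
    j <- which.max(abs(U[, k]))
    if (U[j, k] < 0) -1 else 1
  }, numeric(1))
  U <- sweep(U, 2, flip, `*`)
  W <- diag(D, length(D)) %*% t(V)           # x~ = D V' x
  W <- sweep(W, 1, flip, `*`)
  dm <- dim(a)
  out <- array(0, dim = c(length(D), dm[2], dm[3]))
  for (e in seq_len(dm[3])) out[, , e] <- W %*% a[, , e]
  new("LatentTrajectories", paths = out, ortho = TRUE, U = U, Ddiag = D,
      tausMs = numeric(0), binMs = trajs@binMs)
}

#' Class-balanced leave-one-channel-out RMSE
#'
#' For each channel `j`, latents are inferred from the other `q - 1`
#' channels and channel `j` is predicted as `C_j E[x | y_-j] + d_j`. The
#' root mean squared error is computed for each behavioral class separately
#' and the class RMSEs are summed. With `reducedP` set, prediction uses only
#' the top `reducedP` orthonormalized factors of the (larger) fit — the
#' reduced-GPFA evaluation.
#'
#' @param params a fitted [GPFAParams-class] (GPFA or FA).
#' @param epochs an [EpochSet-class] or `[q, T, E]` array, disjoint from the
#'   training data.
#' @param labels class label per epoch.
#' @param reducedP optional number of orthonormal factors for reduced
#'   prediction.
#' @return list with `total` (sum of class RMSEs) and `perClass`.
#' @export
looRMSE <- function(params, epochs, labels, reducedP = NULL) {
  a <- asEpochArray(epochs)
  dm <- dim(a)
  q <- dm[1]; Tn <- dm[2]; E <- dm[3]
  stopifnot(length(labels) == E, q == nrow(params@C))
  isGP <- length(params@tausMs) > 0
  if (!is.null(reducedP)) {
    sv <- svd(params@C)
    U <- sv$u; W <- diag(sv$d, length(sv$d)) %*% t(sv$v)
    reducedP <- min(reducedP, ncol(U))
  }
  classes <- sort(unique(labels))
  ss <- stats::setNames(numeric(length(classes)), classes)
  nn <- ss
  for (j in seq_len(q)) {
    Cm <- params@C[-j, , drop = FALSE]
    Rm <- params@R[-j]
    dmn <- params@d[-j]
    op <- if (isGP && ncol(Cm) > 0)
      gpfaOperator(Cm, Rm, params@tausMs, params@sigmaNSq, Tn, params@binMs)
    for (e in seq_len(E)) {
      y <- a[, , e]
      m <- if (ncol(Cm) == 0) matrix(0, 0, Tn)
        else if (isGP)
          gpfaPosteriorMean(op, Cm, Rm, dmn, y[-j, , drop = FALSE])$mean
        else faPosteriorMeans(Cm, Rm, dmn, y[-j, , drop = FALSE])
      pred <- if (ncol(Cm) == 0) rep(params@d[j], Tn)
        else if (is.null(reducedP))
          as.vector(params@C[j, , drop = FALSE] %*% m) + params@d[j]
        else
          as.vector(U[j, seq_len(reducedP), drop = FALSE] %*%
                      (W %*% m)[seq_len(reducedP), , drop = FALSE]) + params@d[j]
      cl <- labels[e]
      ss[cl] <- ss[cl] + sum((y[j, ] - pred)^2)
      nn[cl] <- nn[cl] + Tn
    }
  }
  perClass <- sqrt(ss / nn)
  list(total = sum(perClass), perClass = perClass)
}

#' Leave-one-channel-out RMSE versus latent dimensionality
#'
#' For each fold of the plan and each dimensionality in `dims`, fits FA,
#' GPFA, and a larger GPFA whose orthonormalized top factors give the
#' reduced-GPFA prediction, on the class-balanced training epochs; evaluates
#' the class-balanced leave-one-channel-out RMSE on the full test fold, and
#' aggregates across folds.
#'
#' @param epochs an [EpochSet-class].
#' @param labels label per epoch (defaults to the EpochSet labels).
#' @param plan a [CVPlan-class].
#' @param dims increasing latent dimensionalities to test.
#' @param seed integer seed (balancing + initialization).
#' @param maxIter EM iteration cap per fit (default 200).
#' @param tol EM convergence tolerance (default 1e-5).
#' @param reducedFrom dimensionality of the larger fit backing the reduced
#'   evaluation (default `max(dims) + 2`).
#' @return list of class `rmseCurve`: data.frame `curve` with per-p mean and
#'   SE of `rmse_fa`, `rmse_gpfa`, `rmse_reduced`, plus the per-fold arrays.
#' @export
rmseCurve <- function(epochs, labels = epochLabels(epochs), plan, dims,
                      seed = 1, maxIter = 200, tol = 1e-5,
                      reducedFrom = max(dims) + 2) {
  stopifnot(!is.unsorted(dims, strictly = TRUE))
  a <- asEpochArray(epochs)
  k <- plan@nFolds
  fa <- gp <- red <- matrix(NA_real_, k, length(dims))
  for (f in seq_len(k)) {
    tr <- balanceClasses(trainIndices(plan, f), labels, seed = seed + f)
    te <- testIndices(plan, f)
    atr <- a[, , tr, drop = FALSE]
    ate <- a[, , te, drop = FALSE]
    lte <- labels[te]
    big <- gpfaFitEM(atr, reducedFrom, maxIter = maxIter, tol = tol,
                     seed = seed, binMs = binMs(epochs))
    for (iP in seq_along(dims)) {
      p <- dims[iP]
      fFA <- faFit(atr, p, maxIter = maxIter, tol = tol, seed = seed,
                   binMs = binMs(epochs))
      fGP <- gpfaFitEM(atr, p, maxIter = maxIter, tol = tol, seed = seed,
                       binMs = binMs(epochs))
      fa[f, iP] <- looRMSE(fFA, ate, lte)$total
      gp[f, iP] <- looRMSE(fGP, ate, lte)$total
      red[f, iP] <- looRMSE(big, ate, lte, reducedP = p)$total
    }
  }
  curve <- data.frame(
    p = dims,
    rmse_fa = colMeans(fa), se_fa = apply(fa, 2, stats::sd) / sqrt(k),
    rmse_gpfa = colMeans(gp), se_gpfa = apply(gp, 2, stats::sd) / sqrt(k),
    rmse_reduced = colMeans(red),
    se_reduced = apply(red, 2, stats::sd) / sqrt(k))
  structure(list(curve = curve, folds = list(fa = fa, gpfa = gp, red = red)),
            class = "rmseCurve")
}

#' Per-fold GPFA fits and latent trajectories for decoding
#'
#' For each fold: fit GPFA on the class-balanced training epochs, then infer
#' latent trajectories for the balanced training and balanced test epochs.
#' The factors extracted in different folds need not correspond; downstream
#' decoding aligns them by timescale rank.
#'
#' @param epochs an [EpochSet-class].
#' @param labels label per epoch (defaults to the EpochSet labels).
#' @param plan a [CVPlan-class].
#' @param p number of latent factors.
#' @param seed integer seed.
#' @param maxIter,tol EM controls.
#' @return list of per-fold lists (`tausMs`, `trainTrajs`, `trainLabels`,
#'   `testTrajs`, `testLabels`, `fit`), of class `gpfaFolds`.
#' @export
gpfaFoldLatents <- function(epochs, labels = epochLabels(epochs), plan, p,
                            seed = 1, maxIter = 200, tol = 1e-5) {
  a <- asEpochArray(epochs)
  out <- lapply(seq_len(plan@nFolds), function(f) {
    sets <- balancedFold(plan, f, labels, seed)
    fit <- gpfaFitEM(a[, , sets$train, drop = FALSE], p, maxIter = maxIter,
                     tol = tol, seed = seed, binMs = binMs(epochs))
    list(tausMs = fit@tausMs,
         trainTrajs = latentPaths(inferLatents(fit, a[, , sets$train, drop = FALSE])),
         trainLabels = labels[sets$train],
         testTrajs = latentPaths(inferLatents(fit, a[, , sets$test, drop = FALSE])),
         testLabels = labels[sets$test],
         fit = fit)
  })
  structure(out, class = "gpfaFolds")
}

#' Decoding accuracy versus number of timescale-ordered factors
#'
#' Within each fold, factors are sorted by fitted timescale (slowest first
#' or fastest first) and the constrained Gaussian classifier is trained and
#' tested with the first `m = 1..p` factors; fold accuracies are averaged
#' per `m`.
#'
#' @param folds a `gpfaFolds` object from [gpfaFoldLatents()].
#' @param order `"slow_first"` or `"fast_first"`.
#' @param sharedCovariance use the pooled-covariance (LDA) control.
#' @return data.frame with `m`, `accuracy`, `se`.
#' @export
factorDecodingCurve <- function(folds, order = c("slow_first", "fast_first"),
                                sharedCovariance = FALSE) {
  order <- match.arg(order)
  p <- length(folds[[1]]$tausMs)
  acc <- matrix(NA_real_, length(folds), p)
  for (f in seq_along(folds)) {
    fd <- folds[[f]]
    ord <- order(fd$tausMs, decreasing = (order == "slow_first"))
    for (m in seq_len(p)) {
      sel <- ord[seq_len(m)]
      acc[f, m] <- evalConstrainedGaussian(
        fd$trainTrajs[sel, , , drop = FALSE], fd$trainLabels,
        fd$testTrajs[sel, , , drop = FALSE], fd$testLabels,
        sharedCovariance = sharedCovariance)
    }
  }
  data.frame(m = seq_len(p), accuracy = colMeans(acc),
             se = apply(acc, 2, stats::sd) / sqrt(length(folds)))
}

#' Decoding accuracy of single factors, slowest to fastest
#'
#' Trains and tests the constrained Gaussian classifier on one latent factor
#' at a time; because the factors extracted in different folds may differ,
#' accuracies are aligned across folds by timescale rank (slowest = rank 1)
#' before averaging.
#'
#' @param folds a `gpfaFolds` object from [gpfaFoldLatents()].
#' @param sharedCovariance use the pooled-covariance (LDA) control.
#' @return data.frame with `rank`, `meanTauMs`, `accuracy`, `se`.
#' @export
singleFactorDecoding <- function(folds, sharedCovariance = FALSE) {
  p <- length(folds[[1]]$tausMs)
  acc <- tau <- matrix(NA_real_, length(folds), p)
  for (f in seq_along(folds)) {
    fd <- folds[[f]]
    ord <- order(fd$tausMs, decreasing = TRUE)    # slowest first
    for (r in seq_len(p)) {
      i <- ord[r]
      tau[f, r] <- fd$tausMs[i]
      acc[f, r] <- evalConstrainedGaussian(
        fd$trainTrajs[i, , , drop = FALSE], fd$trainLabels,
        fd$testTrajs[i, , , drop = FALSE], fd$testLabels,
        sharedCovariance = sharedCovariance)
    }
  }
  data.frame(rank = seq_len(p), meanTauMs = colMeans(tau),
             accuracy = colMeans(acc),
             se = apply(acc, 2, stats::sd) / sqrt(length(folds)))
}
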