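# Factor analysis by EM on time-pooled bins: the baseline model in which
# every time point is independent, and the initializer for the GPFA fit.

# Gaussian-kernel smoothing along time of each epoch's rows (used by the
# smoothed-FA control); sdMs = 0 or NULL is the identity.
smoothEpochs <- function(a, sdMs, binMs) {
  if (is.null(sdMs) || sdMs <= 0) return(a)
  sdBins <- sdMs / binMs
  half <- max(1L, ceiling(3 * sdBins))
  k <- stats::dnorm(seq(-half, half), sd = sdBins)
  d <- dim(a)
  pad <- function(v) c(rep(v[1], half), v, rep(v[length(v)], half))
  for (e in seq_len(d[3])) for (j in seq_len(d[1])) {
    v <- stats::filter(pad(a[j, , e]), k / sum(k), sides = 2)
    a[j, , e] <- v[(half + 1):(half + d[2])]
  }
  a
}

asEpochArray <- function(epochs) {
  if (is(epochs, "EpochSet")) epochs@epochs else epochs
}

#' Fit factor analysis by EM
#'
#' Standard factor analysis (`y ~ N(d + C x, R)`, `x ~ N(0, I)`, diagonal
#' `R`) fit by EM on bins pooled across time and epochs, optionally after
#' Gaussian-kernel smoothing of each epoch (the smoothed-FA control for
#' testing whether one universal autocorrelation suffices).
#'
#' @param epochs an [EpochSet-class] or `[q, T, E]` array.
#' @param p latent dimensionality (`0 <= p < q`); `p = 0` gives the pure
#'   diagonal-noise model.
#' @param preSmoothMs optional Gaussian smoothing kernel SD in ms (0/`NULL`
#'   disables).
#' @param maxIter maximum EM iterations (default 500).
#' @param tol relative log-likelihood gain for convergence (default 1e-6).
#' @param seed integer seed (kept for interface symmetry; the initializer is
#'   deterministic in the data).
#' @param binMs bin width (ms) when `epochs` is a bare array.
#' @return A [GPFAParams-class] with empty `tausMs`.
#' @export
faFit <- function(epochs, p, preSmoothMs = NULL, maxIter = 500, tol = 1e-6,
                  seed = 1, binMs = 250) {
  if (is(epochs, "EpochSet")) binMs <- epochs@binMs
  a <- asEpochArray(epochs)
  a <- smoothEpochs(a, preSmoothMs, binMs)
  Y <- flattenEpochs(a)
  q <- nrow(Y); N <- ncol(Y)
  if (p >= q) stop("p must be smaller than the number of channels")
  d <- rowMeans(Y)
  S <- stats::cov(t(Y)) * (N - 1) / N       # ML covariance
  varFloor <- 1e-8 * pmax(diag(S), 1e-12)

  llOf <- function(C, R) {
    Sig <- tcrossprod(C) + diag(R, q)
    L <- cholSafe(Sig)
    quad <- sum(diag(backsolve(L, forwardsolve(t(L), S))))
    -N / 2 * (q * log(2 * pi) + 2 * sum(log(diag(L))) + quad)
  }

  if (p == 0) {
    R <- pmax(diag(S), varFloor)
    ll <- llOf(matrix(0, q, 0), R)
    return(new(Class = "GPFAParams", C = matrix(0, q, 0), d = d, R = R,
               tausMs = numeric(0), sigmaNSq = 1e-3, binMs = binMs,
               fitLog = ll, converged = TRUE))
  }

  set.seed(seed)
  eg <- eigen(S, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  resid <- if (p < q) mean(ev[(p + 1):q]) else 0
  C <- eg$vectors[, seq_len(p), drop = FALSE] %*%
    diag(sqrt(pmax(ev[seq_len(p)] - resid, 1e-6)), p)
  R <- pmax(diag(S) - rowSums(C^2), varFloor)

  fitLog <- numeric(0); converged <- FALSE
  for (it in seq_len(maxIter)) {
    ll <- llOf(C, R)
    fitLog <- c(fitLog, ll)
    if (it > 1) {
      gain <- (ll - fitLog[it - 1]) / abs(fitLog[it - 1])
      if (abs(gain) < tol) { converged <- TRUE; break }
    }
    CRi <- C / R                              # R^-1 C, q x p
    G <- solve(diag(p) + crossprod(C, CRi))   # (I + C'R^-1C)^-1
    beta <- tcrossprod(G, CRi)                # p x q, = G C'R^-1
    gamma <- S %*% t(beta)                    # q x p, E[y x']
    delta <- beta %*% gamma + G               # p x p, E[xx']
    C <- gamma %*% solve(delta)
    R <- pmax(diag(S) - rowSums(C * gamma), varFloor)
  }
  if (!converged)
    warning("factor analysis EM did not converge within maxIter")
  new(Class = "GPFAParams", C = C, d = d, R = R, tausMs = numeric(0),
      sigmaNSq = 1e-3, binMs = binMs, fitLog = fitLog, converged = converged)
}
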