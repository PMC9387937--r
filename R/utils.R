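# Internal numerical helpers shared across modules.

# Analytic signal via the frequency-domain construction: double positive
# frequencies, zero negative ones, keep DC (and Nyquist for even n).
analyticSignal <- function(x) {
  n <- length(x)
  if (n < 2) return(complex(real = x, imaginary = rep(0, n)))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Magnitude of the analytic signal (the Hilbert envelope).
envelopeOf <- function(x) Mod(analyticSignal(x))

# Squared-exponential GP kernel over T bins with unit marginal variance:
# K(t1,t2) = (1 - sigmaNSq) exp(-(t1-t2)^2 / (2 tau^2)) + sigmaNSq 1[t1=t2].
gpKernel <- function(tauMs, Tn, binMs, sigmaNSq = 1e-3) {
  t <- (seq_len(Tn) - 1) * binMs
  D <- outer(t, t, "-")
  K <- (1 - sigmaNSq) * exp(-D^2 / (2 * tauMs^2))
  diag(K) <- diag(K) + sigmaNSq
  K
}

# Cholesky with escalating jitter; K is symmetric PSD up to rounding.
cholSafe <- function(K) {
  jit <- 0
  for (i in 0:6) {
    L <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(L)
    jit <- if (jit == 0) 1e-10 * mean(diag(K)) else jit * 10
  }
  stop("Cholesky factorization failed even with jitter")
}

# Zero-phase Butterworth filtering of a vector. type as in signal::butter.
zeroPhaseButter <- function(x, order, W, type) {
  bf <- signal::butter(order, W, type = type)
  as.numeric(signal::filtfilt(bf, x))
}

# 1/f ("pink") noise of length n with unit variance, shaped in the frequency
# domain (amplitude ~ 1/sqrt(f), DC removed).
pinkNoise <- function(n) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)          # two-sided frequency index
  shape <- 1 / sqrt(f)
  shape[1] <- 0
  x <- Re(stats::fft(X * shape, inverse = TRUE) / n)
  as.numeric(scale(x))
}

# Draw epoch-major [q, T, E] array into a q x (T*E) matrix (bins concatenated
# across epochs, epoch-major order).
flattenEpochs <- function(a) {
  d <- dim(a)
  dim(a) <- c(d[1], d[2] * d[3])
  a
}
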