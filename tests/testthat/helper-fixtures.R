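# Fixture builders shared across test files; everything is generated in code.

# EpochSet built directly from a known GPFA generative model:
# y = C x + d + noise, x ~ GP(tausMs). Labels alternate over the classes so
# blocked folds always contain every class.
makeGpfaEpochSet <- function(q = 10, tausMs = c(2000, 6000), Tn = 60, E = 24,
                             classes = c("A", "B"), seed = 1,
                             C = NULL, d = NULL, R = NULL, binMs = 250) {
  set.seed(seed)
  p <- length(tausMs)
  if (is.null(C)) C <- matrix(stats::rnorm(q * p, sd = 0.8), q, p)
  if (is.null(d)) d <- stats::rnorm(q)
  if (is.null(R)) R <- stats::runif(q, 0.2, 0.5)
  a <- array(0, dim = c(q, Tn, E))
  for (e in seq_len(E))
    a[, , e] <- C %*% sampleGPLatents(tausMs, Tn, binMs) + d +
      matrix(stats::rnorm(q * Tn, sd = sqrt(R)), q, Tn)
  epochS <- Tn * binMs / 1000
  new("EpochSet", epochs = a,
      labels = rep(classes, length.out = E),
      epochStartBin = as.integer((seq_len(E) - 1) * Tn + 1),
      epochStartS = (seq_len(E) - 1) * epochS,
      binMs = binMs, channelIds = sprintf("ch%02d", seq_len(q)),
      subjectTag = "synthetic")
}

# Two StateSpecs differing only in loading sign (pure covariance contrast).
pureCovSpecs <- function(q = 8, tauMs = 2000, scale = 1.2) {
  pos <- rep(1, q) / sqrt(q)
  alt <- rep(c(1, -1), length.out = q) / sqrt(q)
  list(
    A = StateSpec("A", rep(3, q), rep(1, q), matrix(pos, q, 1), tauMs,
                  sqrt(q) * scale),
    B = StateSpec("B", rep(3, q), rep(1, q), matrix(alt, q, 1), tauMs,
                  sqrt(q) * scale))
}

# Principal angle (degrees) between the column spaces of A and B.
subspaceAngleDeg <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(min(1, min(s))) * 180 / pi
}

# Independent multivariate normal log-density via eigen decomposition
# (oracle path, deliberately different from the package's chol route).
mvnLogDensityEigen <- function(x, mu, Sigma) {
  e <- eigen(Sigma, symmetric = TRUE)
  z <- crossprod(e$vectors, x - mu)
  -0.5 * (length(x) * log(2 * pi) + sum(log(e$values)) +
            sum(z^2 / e$values))
}
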