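# Epoch features: 30-second tiling of labeled blocks, per-epoch mean and
# variance, covariance matrices, slow/fast band-limited-power split at
# 0.333 Hz, and Welch power spectral densities of the binned envelope.

#' Tile labeled blocks into fixed-length epochs
#'
#' Cuts non-overlapping consecutive `epochS`-second epochs within each
#' labeled block, anchored at the block's first available bin. Epochs that
#' would cross a contiguous-segment boundary are discarded; chronological
#' order is preserved.
#'
#' @param env an [EnvelopeSeries-class].
#' @param blocks data.frame (`start_s`, `end_s`, `state`) of non-overlapping
#'   labeled blocks.
#' @param epochS epoch duration in seconds (default 30).
#' @param subjectTag free-text tag stored on the result.
#' @return An [EpochSet-class].
#' @export
epochEnvelope <- function(env, blocks, epochS = 30, subjectTag = "") {
  ord <- order(blocks$start_s)
  blocks <- blocks[ord, ]
  if (any(blocks$start_s[-1] < blocks$end_s[-nrow(blocks)] - 1e-9))
    stop("blocks must be non-overlapping")
  eb <- as.integer(round(epochS * 1000 / env@binMs))
  segId <- integer(ncol(env@values))
  for (i in seq_along(env@segmentBounds)) {
    b <- env@segmentBounds[[i]]
    segId[seq(b[1], b[2])] <- i
  }
  epochs <- list(); labs <- character(); startBin <- integer()
  for (b in seq_len(nrow(blocks))) {
    idx <- which(env@binTimeS >= blocks$start_s[b] - 1e-9 &
                   env@binTimeS < blocks$end_s[b] - 1e-9)
    if (length(idx) < eb) next
    nE <- length(idx) %/% eb
    for (e in seq_len(nE)) {
      bi <- idx[((e - 1) * eb + 1):(e * eb)]
      if (bi[eb] - bi[1] != eb - 1L) next              # index gap
      if (segId[bi[1]] != segId[bi[eb]]) next          # crosses segments
      epochs[[length(epochs) + 1]] <- env@values[, bi, drop = FALSE]
      labs <- c(labs, blocks$state[b])
      startBin <- c(startBin, bi[1])
    }
  }
  if (!length(epochs)) stop("no complete epochs could be tiled")
  arr <- array(unlist(epochs), dim = c(nrow(env@values), eb, length(epochs)))
  new("EpochSet", epochs = arr, labels = labs,
      epochStartBin = as.integer(startBin),
      epochStartS = env@binTimeS[startBin], binMs = env@binMs,
      channelIds = env@channelIds, subjectTag = subjectTag)
}

#' Per-epoch channel means and variances
#'
#' @param es an [EpochSet-class].
#' @return numeric matrix `[E x 2q]`: per-channel means then per-channel
#'   sample variances, columns named `mean.<ch>` / `var.<ch>`.
#' @export
epochMeanVar <- function(es) {
  a <- es@epochs
  m <- t(apply(a, c(1, 3), mean))
  v <- t(apply(a, c(1, 3), stats::var))
  out <- cbind(m, v)
  colnames(out) <- c(paste0("mean.", es@channelIds),
                     paste0("var.", es@channelIds))
  out
}

#' Per-epoch channel covariance matrices
#'
#' Sample covariance of each epoch's `q x T` data; intended for epochs cut
#' from a z-scored envelope so class differences in long-term channel
#' variances are removed first.
#'
#' @param es an [EpochSet-class].
#' @return numeric array `[q, q, E]` of symmetric covariance matrices.
#' @export
epochCovariance <- function(es) {
  d <- dim(es@epochs)
  if (d[1] > d[2])
    warning("more channels than bins per epoch: covariance is rank-deficient")
  out <- array(0, dim = c(d[1], d[1], d[3]))
  for (e in seq_len(d[3]))
    out[, , e] <- stats::cov(t(es@epochs[, , e]))
  out
}

#' Slow/fast band-limited-power features
#'
#' Splits the (z-scored) binned envelope at `fc` into slow and fast
#' components (zero-phase 4th-order Butterworth low/high pass at the 4 Hz
#' bin rate), takes the magnitude of each component's analytic signal, and
#' averages it within the same 30-second epoch grid as [epochEnvelope()].
#' Epochs in segments too short for stable filtering are dropped with a
#' message.
#'
#' @param env a z-scored [EnvelopeSeries-class].
#' @param blocks labeled blocks as in [epochEnvelope()].
#' @param fc cutoff frequency in Hz (default 1/3, a 3-second period).
#' @param epochS epoch duration (s), default 30.
#' @return list with `slow` and `fast` (`[E x q]` feature matrices),
#'   `labels`, and `epochStartS`.
#' @export
bandsplitEnvelope <- function(env, blocks, fc = 1 / 3, epochS = 30) {
  fsBin <- 1000 / env@binMs
  W <- fc / (fsBin / 2)
  ord <- 4
  minLen <- 3 * (2 * ord + 1)          # filtfilt warm-up
  q <- nrow(env@values); Tn <- ncol(env@values)
  slowM <- matrix(NA_real_, q, Tn)
  fastM <- matrix(NA_real_, q, Tn)
  for (seg in env@segmentBounds) {
    idx <- seq(seg[1], seg[2])
    if (length(idx) <= minLen) {
      message(sprintf("segment of %d bins too short for band splitting; dropped",
                      length(idx)))
      next
    }
    for (j in seq_len(q)) {
      v <- env@values[j, idx]
      slowM[j, idx] <- envelopeOf(zeroPhaseButter(v, ord, W, "low"))
      fastM[j, idx] <- envelopeOf(zeroPhaseButter(v, ord, W, "high"))
    }
  }
  es <- epochEnvelope(env, blocks, epochS = epochS)
  eb <- dim(es@epochs)[2]
  E <- nEpochs(es)
  slow <- matrix(0, E, q); fast <- matrix(0, E, q)
  keep <- rep(TRUE, E)
  for (e in seq_len(E)) {
    bi <- es@epochStartBin[e] + seq_len(eb) - 1L
    s <- rowMeans(slowM[, bi, drop = FALSE])
    f <- rowMeans(fastM[, bi, drop = FALSE])
    if (any(!is.finite(s)) || any(!is.finite(f))) keep[e] <- FALSE
    else { slow[e, ] <- s; fast[e, ] <- f }
  }
  colnames(slow) <- colnames(fast) <- env@channelIds
  list(slow = slow[keep, , drop = FALSE], fast = fast[keep, , drop = FALSE],
       labels = es@labels[keep], epochStartS = es@epochStartS[keep])
}

#' Welch power spectral density of the binned envelope, by state
#'
#' Estimates the PSD of each channel within each behavioral state by Welch's
#' method over the state's concatenated 30-second epochs: Hann-windowed
#' segments the length of one epoch (120 bins) with 75% overlap, zero-padded
#' to `nfft` points, periodograms averaged; the standard error is computed
#' across periodograms before averaging. Frequencies run from 0 to the bin
#' Nyquist (2 Hz at 250 ms bins).
#'
#' @param es an [EpochSet-class] (typically of the z-scored envelope).
#' @param nfft FFT length (default 256).
#' @param overlap fractional window overlap (default 0.75).
#' @return data.frame with columns `freq`, `power`, `se`, `channel`,
#'   `state`; `se` is `NA` when a state yields fewer than 2 windows.
#' @export
welchPSD <- function(es, nfft = 256, overlap = 0.75) {
  fs <- 1000 / es@binMs
  Tw <- dim(es@epochs)[2]
  if (nfft < Tw) stop("nfft must be at least the window length")
  w <- as.numeric(signal::hanning(Tw))
  hop <- max(1L, as.integer(round(Tw * (1 - overlap))))
  nb <- nfft %/% 2 + 1
  freq <- (seq_len(nb) - 1) * fs / nfft
  scaleF <- 1 / (fs * sum(w^2))
  out <- list()
  for (st in unique(es@labels)) {
    x <- flattenEpochs(es@epochs[, , es@labels == st, drop = FALSE])
    starts <- seq(1, ncol(x) - Tw + 1, by = hop)
    for (j in seq_len(nrow(x))) {
      P <- matrix(0, length(starts), nb)
      for (i in seq_along(starts)) {
        seg <- x[j, starts[i] + seq_len(Tw) - 1] * w
        X <- stats::fft(c(seg, numeric(nfft - Tw)))
        p <- Mod(X[seq_len(nb)])^2 * scaleF
        p[2:(nb - 1)] <- 2 * p[2:(nb - 1)]   # one-sided
        P[i, ] <- p
      }
      se <- if (nrow(P) >= 2) apply(P, 2, stats::sd) / sqrt(nrow(P)) else NA_real_
      out[[length(out) + 1]] <- data.frame(
        freq = freq, power = colMeans(P), se = se,
        channel = es@channelIds[j], state = st, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
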