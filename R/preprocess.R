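# Signal conditioning: raw multichannel recordings -> 250 ms binned
# high-gamma amplitude with channel rejection, referencing, notch filtering,
# despiking, and per-window z-scoring.

#' Reject noise-corrupted channels by squared-signal power
#'
#' A channel is rejected when its mean squared signal value exceeds the mean
#' across channels by more than `k` standard deviations (computed across
#' channels), with `k = 3` for ECoG and `k = 1.5` for sEEG. Channels
#' containing values exactly equal to zero are also rejected.
#'
#' @param raw a [RawRecording-class] with at least 3 channels.
#' @param modality `"ecog"` or `"seeg"`; defaults to the recording's tag.
#' @return data.frame (`channel_id`, `keep`, `reason`) with `reason` one of
#'   `""`, `"power"`, `"zeros"`.
#' @export
rejectChannels <- function(raw, modality = raw@modality) {
  x <- raw@samples
  if (nrow(x) < 3) stop("channel rejection needs at least 3 channels")
  k <- if (modality == "ecog") 3 else 1.5
  msq <- rowMeans(x^2)
  thr <- mean(msq) + k * stats::sd(msq)
  keep <- msq <= thr
  reason <- ifelse(keep, "", "power")
  zeros <- apply(x, 1, function(v) any(v == 0))
  reason[zeros] <- "zeros"
  keep <- keep & !zeros
  if (!any(keep)) stop("all channels rejected")
  if (sum(keep) < 2)
    warning("fewer than 2 channels kept; covariance analyses unavailable")
  data.frame(channel_id = raw@channelIds, keep = keep, reason = reason,
             stringsAsFactors = FALSE)
}

#' Subset a recording to the kept channels of a mask
#'
#' @param raw a [RawRecording-class].
#' @param mask data.frame from [rejectChannels()].
#' @return A [RawRecording-class] with rejected channels dropped.
#' @export
applyChannelMask <- function(raw, mask) {
  keep <- mask$keep[match(raw@channelIds, mask$channel_id)]
  RawRecording(raw@samples[keep, , drop = FALSE], fsHz = raw@fsHz,
               channelIds = raw@channelIds[keep], modality = raw@modality)
}

#' Re-reference a recording
#'
#' `"common_average"` subtracts the instantaneous mean across channels
#' (the ECoG scheme); `"bipolar_pairs"` differences adjacent contacts along
#' each shank (the sEEG scheme), producing `q - nShanks` channels labeled
#' `"A1-A2"` style.
#'
#' @param raw a [RawRecording-class].
#' @param scheme `"common_average"` or `"bipolar_pairs"`.
#' @param shanks for bipolar: character/factor of length `q` naming the
#'   shank of each channel, channels ordered along each shank.
#' @return A re-referenced [RawRecording-class].
#' @export
rereference <- function(raw, scheme = c("common_average", "bipolar_pairs"),
                        shanks = NULL) {
  scheme <- match.arg(scheme)
  x <- raw@samples
  if (scheme == "common_average") {
    out <- sweep(x, 2, colMeans(x))
    return(RawRecording(out, fsHz = raw@fsHz, channelIds = raw@channelIds,
                        modality = raw@modality))
  }
  if (is.null(shanks) || length(shanks) != nrow(x))
    stop("bipolar referencing requires a shank label per channel, ordered along shanks")
  shanks <- as.character(shanks)
  rows <- list(); ids <- character()
  for (s in unique(shanks)) {
    idx <- which(shanks == s)
    if (length(idx) < 2) next
    for (i in seq_len(length(idx) - 1)) {
      a <- idx[i]; b <- idx[i + 1]
      rows[[length(rows) + 1]] <- x[a, ] - x[b, ]
      ids <- c(ids, paste0(raw@channelIds[a], "-", raw@channelIds[b]))
    }
  }
  if (!length(rows)) stop("no bipolar pairs could be formed")
  RawRecording(do.call(rbind, rows), fsHz = raw@fsHz, channelIds = ids,
               modality = raw@modality)
}

#' Notch-filter line noise and harmonics
#'
#' Zero-phase (forward-backward) 2nd-order Butterworth band-stop per center
#' frequency. Centers at or above Nyquist are dropped with a warning.
#'
#' @param raw a [RawRecording-class].
#' @param centers center frequencies (Hz), default 60/120/180/240.
#' @param bandwidthHz stop-band width (Hz), default 1.
#' @return The filtered [RawRecording-class].
#' @export
notchFilter <- function(raw, centers = c(60, 120, 180, 240),
                        bandwidthHz = 1) {
  nyq <- raw@fsHz / 2
  drop <- centers + bandwidthHz / 2 >= nyq
  if (any(drop)) {
    warning(sprintf("dropping notch centers at/above Nyquist: %s",
                    paste(centers[drop], collapse = ", ")))
    centers <- centers[!drop]
  }
  x <- raw@samples
  for (f0 in centers) {
    W <- c(f0 - bandwidthHz / 2, f0 + bandwidthHz / 2) / nyq
    bf <- signal::butter(2, W, type = "stop")
    for (j in seq_len(nrow(x)))
      x[j, ] <- signal::filtfilt(bf, x[j, ])
  }
  RawRecording(x, fsHz = raw@fsHz, channelIds = raw@channelIds,
               modality = raw@modality)
}

#' Downsample a recording with anti-aliasing
#'
#' Low-pass filters at 0.8 x the target Nyquist (zero-phase, 8th-order
#' Butterworth) and decimates by the integer ratio `fs / targetFs`.
#'
#' @param raw a [RawRecording-class].
#' @param targetFs target sampling rate (Hz), default 500; must divide the
#'   current rate.
#' @return The downsampled [RawRecording-class].
#' @export
downsampleRecording <- function(raw, targetFs = 500) {
  ratio <- raw@fsHz / targetFs
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("sampling-rate ratio must be an integer")
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(raw)
  W <- 0.8 * (targetFs / 2) / (raw@fsHz / 2)
  x <- raw@samples
  out <- matrix(0, nrow(x), floor(ncol(x) / ratio))
  keep <- seq(1, by = ratio, length.out = ncol(out))
  for (j in seq_len(nrow(x)))
    out[j, ] <- zeroPhaseButter(x[j, ], 8, W, "low")[keep]
  RawRecording(out, fsHz = targetFs, channelIds = raw@channelIds,
               modality = raw@modality)
}

#' Extract the binned band-limited amplitude (high-gamma envelope)
#'
#' Per channel: zero-phase 4th-order Butterworth band-pass, magnitude of the
#' analytic signal, then the mean over consecutive non-overlapping bins
#' (128 samples at 512 Hz, 125 at 500 Hz for 250 ms bins). The average
#' amplitude per bin estimates the square root of band power. A trailing
#' partial bin is dropped.
#'
#' @param raw a [RawRecording-class].
#' @param band two-element pass band (Hz), default `c(70, 110)`; must lie in
#'   `(0, fs/2)`.
#' @param binMs bin width (ms), default 250.
#' @return An [EnvelopeSeries-class].
#' @export
extractEnvelope <- function(raw, band = c(70, 110), binMs = 250) {
  nyq <- raw@fsHz / 2
  if (band[1] <= 0 || band[2] >= nyq) stop("band must lie inside (0, fs/2)")
  spb <- raw@fsHz * binMs / 1000
  if (abs(spb - round(spb)) > 1e-9)
    stop("binMs must be an integer number of samples at this rate")
  spb <- as.integer(round(spb))
  n <- ncol(raw@samples)
  nb <- n %/% spb
  if (nb < 1) stop("recording shorter than one bin")
  W <- band / nyq
  q <- nrow(raw@samples)
  vals <- matrix(0, q, nb)
  for (j in seq_len(q)) {
    bp <- zeroPhaseButter(raw@samples[j, ], 4, W, "pass")
    ev <- envelopeOf(bp)[seq_len(nb * spb)]
    vals[j, ] <- colMeans(matrix(ev, spb, nb))
  }
  EnvelopeSeries(vals, binMs = binMs, channelIds = raw@channelIds)
}

#' Replace envelope amplitude spikes by interpolation
#'
#' Within each contiguous segment and channel, bins exceeding `k` times the
#' channel's segment median are replaced by linear interpolation between the
#' nearest non-flagged neighbors; flagged bins at segment edges take the
#' nearest non-flagged value.
#'
#' @param env an [EnvelopeSeries-class].
#' @param k threshold multiple of the median (default 7).
#' @return The despiked [EnvelopeSeries-class].
#' @export
despikeEnvelope <- function(env, k = 7) {
  vals <- env@values
  for (seg in env@segmentBounds) {
    idx <- seq(seg[1], seg[2])
    for (j in seq_len(nrow(vals))) {
      v <- vals[j, idx]
      flagged <- v > k * stats::median(v)
      if (!any(flagged)) next
      if (all(flagged))
        stop("all bins flagged in a segment; cannot interpolate")
      good <- which(!flagged)
      v[flagged] <- stats::approx(good, v[good], xout = which(flagged),
                                  rule = 2)$y
      vals[j, idx] <- v
    }
  }
  EnvelopeSeries(vals, binMs = env@binMs, binTimeS = env@binTimeS,
                 segmentBounds = env@segmentBounds,
                 channelIds = env@channelIds)
}

#' Z-score the envelope across fixed windows
#'
#' Per channel and window, subtracts the window mean and divides by the
#' window sample standard deviation (denominator `n - 1`). Windows follow
#' the labeled 5-minute blocks when `blocks` is supplied; otherwise
#' `windowS`-second windows are tiled from each segment start (a trailing
#' partial window is z-scored as-is). A zero-variance window is set to 0
#' with a warning.
#'
#' @param env an [EnvelopeSeries-class].
#' @param windowS window length in seconds (default 300).
#' @param blocks optional data.frame (`start_s`, `end_s`, `state`) whose
#'   boundaries define the windows.
#' @return The z-scored [EnvelopeSeries-class].
#' @export
zscoreSegments <- function(env, windowS = 300, blocks = NULL) {
  vals <- env@values
  windows <- list()
  if (!is.null(blocks)) {
    for (b in seq_len(nrow(blocks))) {
      idx <- which(env@binTimeS >= blocks$start_s[b] &
                     env@binTimeS < blocks$end_s[b])
      if (length(idx)) windows[[length(windows) + 1]] <- idx
    }
  } else {
    wb <- as.integer(round(windowS * 1000 / env@binMs))
    for (seg in env@segmentBounds) {
      starts <- seq(seg[1], seg[2], by = wb)
      for (s in starts)
        windows[[length(windows) + 1]] <- seq(s, min(s + wb - 1, seg[2]))
    }
  }
  for (idx in windows) {
    for (j in seq_len(nrow(vals))) {
      v <- vals[j, idx]
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0) {
        warning(sprintf("zero-variance window for channel %s; set to 0",
                        env@channelIds[j]))
        vals[j, idx] <- 0
      } else {
        vals[j, idx] <- (v - mean(v)) / s
      }
    }
  }
  EnvelopeSeries(vals, binMs = env@binMs, binTimeS = env@binTimeS,
                 segmentBounds = env@segmentBounds,
                 channelIds = env@channelIds)
}

#' Full conditioning chain: raw recording to despiked envelope
#'
#' Order of operations: channel rejection, re-referencing (common average
#' for ECoG, bipolar for sEEG), downsampling to 500 Hz for sEEG, notch
#' filtering at 60/120/180/240 Hz, band-pass + Hilbert envelope + 250 ms
#' binning, despiking at 7 x the channel median.
#'
#' @param raw a [RawRecording-class].
#' @param shanks shank labels for bipolar referencing (sEEG only).
#' @param band high-gamma band, default `c(70, 110)` Hz.
#' @param binMs bin width (ms), default 250.
#' @param rejectOnReferenced if `TRUE` (default) the power-threshold
#'   rejection runs on the referenced signals, else on the raw input.
#' @return list with `env` ([EnvelopeSeries-class]) and `mask` (the channel
#'   rejection table).
#' @export
preprocessRecording <- function(raw, shanks = NULL, band = c(70, 110),
                                binMs = 250, rejectOnReferenced = TRUE) {
  scheme <- if (raw@modality == "ecog") "common_average" else "bipolar_pairs"
  if (rejectOnReferenced) {
    stage <- rereference(raw, scheme, shanks)
    mask <- rejectChannels(stage)
    stage <- applyChannelMask(stage, mask)
  } else {
    mask <- rejectChannels(raw)
    stage <- applyChannelMask(raw, mask)
    if (!is.null(shanks)) shanks <- shanks[mask$keep]
    stage <- rereference(stage, scheme, shanks)
  }
  if (raw@modality == "seeg" && stage@fsHz > 500)
    stage <- downsampleRecording(stage, 500)
  stage <- notchFilter(stage)
  env <- extractEnvelope(stage, band = band, binMs = binMs)
  env <- despikeEnvelope(env, k = 7)
  list(env = env, mask = mask)
}
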