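# Synthetic-data module: multichannel envelope and raw-recording generation
# with planted state-dependent statistics, for end-to-end verification of the
# conditioning, feature, and decoding chain without patient data.

#' Sample latent Gaussian-process factor trajectories
#'
#' Draws `p` independent zero-mean Gaussian-process rows over `Tn` bins, one
#' per entry of `tausMs`. Row `i` has the squared-exponential covariance
#' `K_i(t1, t2) = (1 - sigmaNSq) exp(-(t1 - t2)^2 / (2 tau_i^2)) +
#' sigmaNSq 1[t1 = t2]`, so each row has unit marginal variance.
#'
#' @param tausMs positive numeric vector of timescales in milliseconds, one
#'   per latent factor.
#' @param Tn number of time bins (>= 1).
#' @param binMs bin width in milliseconds (default 250).
#' @param sigmaNSq kernel noise floor (default 1e-3).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return numeric matrix `[p x Tn]` of latent trajectories.
#' @examples
#' x <- sampleGPLatents(c(500, 5000), Tn = 120, seed = 1)
#' @export
sampleGPLatents <- function(tausMs, Tn, binMs = 250, sigmaNSq = 1e-3,
                            seed = NULL) {
  if (any(tausMs <= 0) || binMs <= 0)
    stop("tausMs and binMs must be positive")
  if (Tn < 1) stop("Tn must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  p <- length(tausMs)
  out <- matrix(0, p, Tn)
  for (tau in unique(tausMs)) {
    rows <- which(tausMs == tau)
    L <- cholSafe(gpKernel(tau, Tn, binMs, sigmaNSq))   # upper triangular
    Z <- matrix(stats::rnorm(length(rows) * Tn), length(rows), Tn)
    out[rows, ] <- Z %*% L
  }
  out
}

#' Build a block schedule of behavioral states
#'
#' @param states character vector of state names; the schedule cycles through
#'   them `repeats` times (so consecutive blocks differ and every fold of a
#'   blocked CV sees every state).
#' @param repeats number of cycles.
#' @param blockLenS block duration in seconds (default 300, i.e. 5 minutes).
#' @return data.frame with columns `state`, `duration_s`.
#' @export
makeSchedule <- function(states, repeats = 7, blockLenS = 300) {
  data.frame(state = rep(states, repeats),
             duration_s = blockLenS, stringsAsFactors = FALSE)
}

#' Default planted state specifications
#'
#' Three behavioral states over `q` channels differing simultaneously in all
#' four properties the analysis probes: channel mean, channel variance,
#' cross-channel covariance sign/strength, and latent timescale. `"dialogue"`
#' carries a slow (8 s) positively-correlated factor, `"electronics"` a
#' medium (1 s) factor with opposite loading sign on half the channels, and
#' `"rest"` a fast (300 ms) weak factor, with distinct means and standard
#' deviations. Envelope units are arbitrary amplitude with a baseline chosen
#' so planted modulations stay large relative to the carrier-envelope
#' estimation noise of a 40 Hz-wide band averaged over 250 ms bins, while
#' values remain essentially positive.
#'
#' @param q number of channels (default 12).
#' @param meanShift separation of state means in envelope units (default 0.8).
#' @param sdRatio multiplicative spread of state standard deviations
#'   (default 1.4).
#' @param baseline baseline envelope amplitude (default 3).
#' @return named list of [StateSpec-class] objects.
#' @export
defaultStateSpecs <- function(q = 12, meanShift = 0.8, sdRatio = 1.4,
                              baseline = 3) {
  signFlip <- rep(c(1, -1), length.out = q)
  pos <- rep(1, q) / sqrt(q)
  specs <- list(
    dialogue = StateSpec(
      name = "dialogue",
      channelMean = rep(baseline, q),
      channelSd = rep(1, q),
      loading = matrix(pos, q, 1),
      tausMs = 8000,
      factorScale = sqrt(q) * 1.8),
    electronics = StateSpec(
      name = "electronics",
      channelMean = rep(baseline + meanShift, q),
      channelSd = rep(sdRatio, q),
      loading = matrix(pos * signFlip, q, 1),
      tausMs = 1000,
      factorScale = sqrt(q) * 1.8),
    rest = StateSpec(
      name = "rest",
      channelMean = rep(baseline - meanShift, q),
      channelSd = rep(1 / sdRatio, q),
      loading = matrix(pos, q, 1),
      tausMs = 300,
      factorScale = sqrt(q) * 0.8))
  specs
}

#' Generate a binned envelope dataset with planted state structure
#'
#' Per bin `t` in a block of state `s`, the generated envelope is
#' `y_t = mean_s + diag(sd_s) (C_s (x_t * scale_s) + eps_t)` with `x_t` the
#' latent Gaussian-process factors (drawn independently per block) and
#' `eps_t` i.i.d. standard normal per channel, so the planted covariance
#' before sd scaling is `C_s diag(scale_s^2) C_s' + I`.
#'
#' @param specs named list of [StateSpec-class]; all must share `q` and the
#'   number of factors.
#' @param schedule data.frame with `state`, `duration_s` columns
#'   (see [makeSchedule()]); every state must resolve to a spec.
#' @param binMs bin width (ms), default 250.
#' @param seed integer seed for reproducibility.
#' @param clip if `TRUE`, clip the envelope at zero from below (realism flag;
#'   default `FALSE` keeps the planted Gaussian structure exact).
#' @param sigmaNSq GP kernel noise floor.
#' @return list with elements `env` ([EnvelopeSeries-class]), `labels`
#'   (data.frame `start_s`, `end_s`, `state`) and `truth` (list with
#'   `latentPaths` `[pTrue x Ttotal]`, `stateOfBin`, `specs`, `seed`).
#' @export
generateEnvelopeDataset <- function(specs, schedule, binMs = 250, seed = 1,
                                    clip = FALSE, sigmaNSq = 1e-3) {
  qs <- vapply(specs, function(s) length(s@channelMean), integer(1))
  ps <- vapply(specs, function(s) ncol(s@loading), integer(1))
  if (length(unique(qs)) != 1) stop("all StateSpecs must share q")
  if (length(unique(ps)) != 1) stop("all StateSpecs must share the factor count")
  if (!all(schedule$state %in% names(specs)))
    stop("every schedule state must resolve to a StateSpec")
  if (any(schedule$duration_s <= 0)) stop("block durations must be positive")
  q <- qs[1]; p <- ps[1]
  set.seed(seed)

  binsPerBlock <- floor(schedule$duration_s * 1000 / binMs)
  Ttot <- sum(binsPerBlock)
  values <- matrix(0, q, Ttot)
  latent <- matrix(0, p, Ttot)
  stateOfBin <- character(Ttot)

  # cache one Cholesky factor per (tau, block length)
  cholCache <- new.env(parent = emptyenv())
  offset <- 0L
  for (b in seq_len(nrow(schedule))) {
    sp <- specs[[schedule$state[b]]]
    Tb <- binsPerBlock[b]
    idx <- offset + seq_len(Tb)
    x <- matrix(0, p, Tb)
    for (i in seq_len(p)) {
      key <- sprintf("%g_%d", sp@tausMs[i], Tb)
      if (is.null(cholCache[[key]]))
        cholCache[[key]] <- cholSafe(gpKernel(sp@tausMs[i], Tb, binMs, sigmaNSq))
      x[i, ] <- stats::rnorm(Tb) %*% cholCache[[key]]
    }
    eps <- matrix(stats::rnorm(q * Tb), q, Tb)
    y <- sp@channelMean + sp@channelSd *
      (sp@loading %*% (x * sp@factorScale) + eps)
    values[, idx] <- y
    latent[, idx] <- x
    stateOfBin[idx] <- sp@name
    offset <- offset + Tb
  }
  if (clip) values[values < 0] <- 0

  blockEnd <- cumsum(schedule$duration_s)
  labels <- data.frame(start_s = c(0, blockEnd[-length(blockEnd)]),
                       end_s = blockEnd,
                       state = schedule$state, stringsAsFactors = FALSE)
  env <- EnvelopeSeries(values, binMs = binMs)
  list(env = env, labels = labels,
       truth = list(latentPaths = latent, stateOfBin = stateOfBin,
                    specs = specs, seed = seed))
}

#' Synthesize a raw recording from a binned envelope
#'
#' Inverse of the conditioning chain: each channel is a band-limited
#' unit-variance noise carrier (independent per channel) amplitude-modulated
#' by the envelope (each bin's amplitude held over its samples), plus 1/f background noise, 60 Hz
#' line noise with harmonics, and sparse one-bin amplitude spikes at ten
#' times the channel median envelope (Poisson arrivals). Running the
#' conditioning chain on the output recovers the input envelope up to affine
#' scaling.
#'
#' @param env an [EnvelopeSeries-class] (e.g. from
#'   [generateEnvelopeDataset()]).
#' @param fsHz target sampling rate; must be an integer number of samples per
#'   bin and at least twice the carrier band top (default 512).
#' @param carrierBand two-element band (Hz) for the carrier, default
#'   `c(70, 110)`.
#' @param noise list of levels: `pinkSd` (1/f noise SD as a fraction of the
#'   channel median envelope), `lineAmp` (60 Hz amplitude, same scale; the
#'   h-th harmonic gets `lineAmp / h`), `spikeRatePerS` (Poisson rate of
#'   amplitude spikes per channel per second), `spikeGain` (spike amplitude
#'   as a multiple of the channel median envelope).
#' @param modality `"ecog"` or `"seeg"` tag for the output.
#' @param carrier `"noise"` (default): white noise band-passed to the
#'   carrier band, the realistic choice whose own envelope fluctuates; or
#'   `"tone"`: a constant-amplitude sinusoid at the band center with random
#'   phase, useful as a distortion-free diagnostic.
#' @param seed optional integer seed.
#' @return A [RawRecording-class].
#' @export
generateRawRecording <- function(env, fsHz = 512, carrierBand = c(70, 110),
                                 noise = list(), modality = "ecog",
                                 carrier = c("noise", "tone"),
                                 seed = NULL) {
  carrier <- match.arg(carrier)
  if (fsHz < 2 * carrierBand[2])
    stop("fsHz below Nyquist for the carrier band")
  spb <- fsHz * env@binMs / 1000
  if (abs(spb - round(spb)) > 1e-9)
    stop("envelope bin width must divide evenly into samples at fsHz")
  spb <- as.integer(round(spb))
  if (!is.null(seed)) set.seed(seed)
  cfg <- utils::modifyList(
    list(pinkSd = 0.15, lineAmp = 0.5, spikeRatePerS = 1 / 300,
         spikeGain = 10), noise)

  vals <- env@values
  q <- nrow(vals); Tn <- ncol(vals)
  n <- Tn * spb
  tSamp <- (seq_len(n) - 0.5) / fsHz
  W <- carrierBand / (fsHz / 2)
  out <- matrix(0, q, n)
  for (j in seq_len(q)) {
    ev <- vals[j, ]
    med <- stats::median(ev)
    # sparse one-bin amplitude spikes
    nSpk <- stats::rpois(1, cfg$spikeRatePerS * Tn * env@binMs / 1000)
    if (nSpk > 0) {
      at <- sample.int(Tn, min(nSpk, Tn))
      ev[at] <- cfg$spikeGain * med
    }
    modAmp <- rep(ev, each = spb)      # zero-order hold: bin value held
                                       # constant over the bin's samples
    car <- if (carrier == "noise") {
      cw <- zeroPhaseButter(stats::rnorm(n), 4, W, "pass")
      cw / stats::sd(cw)
    } else {
      sqrt(2) * sin(2 * pi * mean(carrierBand) * tSamp +
                      stats::runif(1, 0, 2 * pi))
    }
    x <- modAmp * car
    if (cfg$pinkSd > 0) x <- x + cfg$pinkSd * abs(med) * pinkNoise(n)
    if (cfg$lineAmp > 0) {
      for (h in 1:4) {
        f <- 60 * h
        if (f < fsHz / 2)
          x <- x + (cfg$lineAmp * abs(med) / h) *
            sin(2 * pi * f * tSamp + stats::runif(1, 0, 2 * pi))
      }
    }
    out[j, ] <- x
  }
  RawRecording(out, fsHz = fsHz, channelIds = env@channelIds,
               modality = modality)
}
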