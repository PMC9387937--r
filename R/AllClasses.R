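#' @import methods
NULL

#' Multichannel raw recording
#'
#' Container for a continuous multichannel intracranial recording
#' (microvolt-scale samples), either subdural grid (`"ecog"`) or depth
#' electrode (`"seeg"`) style.
#'
#' @slot samples numeric matrix, channels x samples.
#' @slot fsHz sampling rate in Hz.
#' @slot channelIds character vector of channel labels.
#' @slot modality `"ecog"` or `"seeg"`.
#' @exportClass RawRecording
setClass("RawRecording",
  representation(samples = "matrix", fsHz = "numeric",
                 channelIds = "character", modality = "character"))

setValidity("RawRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@samples)) msg <- c(msg, "samples must be numeric")
  if (any(!is.finite(object@samples))) msg <- c(msg, "samples must be finite")
  if (length(object@fsHz) != 1L || object@fsHz <= 0)
    msg <- c(msg, "fsHz must be a single positive number")
  if (length(object@channelIds) != nrow(object@samples))
    msg <- c(msg, "channelIds length must match number of channel rows")
  if (!object@modality %in% c("ecog", "seeg"))
    msg <- c(msg, "modality must be 'ecog' or 'seeg'")
  if (length(msg)) msg else TRUE
})

#' Construct a RawRecording
#'
#' @param samples numeric matrix, channels x samples.
#' @param fsHz sampling rate (Hz).
#' @param channelIds channel labels; defaults to `ch01, ch02, ...`.
#' @param modality `"ecog"` or `"seeg"`.
#' @return A [RawRecording-class] object.
#' @export
RawRecording <- function(samples, fsHz, channelIds = NULL, modality = "ecog") {
  if (is.null(channelIds))
    channelIds <- sprintf("ch%02d", seq_len(nrow(samples)))
  new("RawRecording", samples = samples, fsHz = fsHz,
      channelIds = channelIds, modality = modality)
}

setMethod("show", "RawRecording", function(object) {
  cat(sprintf("RawRecording: %d channels x %d samples @ %g Hz (%s), %.1f s\n",
              nrow(object@samples), ncol(object@samples), object@fsHz,
              object@modality, ncol(object@samples) / object@fsHz))
})

#' Binned band-limited amplitude series
#'
#' Channels x time-bins matrix of high-gamma (or other band) amplitude
#' estimates, binned at `binMs` (250 ms by default, i.e. 4 Hz), together with
#' the wall-clock start time of every bin and the partition of bins into
#' contiguous recording segments. Filtering and epoch tiling never cross
#' segment boundaries.
#'
#' @slot values numeric matrix, channels x bins.
#' @slot binMs bin width in milliseconds.
#' @slot binTimeS numeric, start time (seconds) of each bin.
#' @slot segmentBounds list of length-2 integer vectors `c(first, last)`
#'   (1-based, inclusive) partitioning the bin axis.
#' @slot channelIds character channel labels.
#' @exportClass EnvelopeSeries
setClass("EnvelopeSeries",
  representation(values = "matrix", binMs = "numeric", binTimeS = "numeric",
                 segmentBounds = "list", channelIds = "character"))

setValidity("EnvelopeSeries", function(object) {
  msg <- character()
  Tn <- ncol(object@values)
  if (any(!is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (length(object@binTimeS) != Tn)
    msg <- c(msg, "binTimeS length must equal number of bins")
  if (length(object@channelIds) != nrow(object@values))
    msg <- c(msg, "channelIds length must match channels")
  covered <- unlist(lapply(object@segmentBounds, function(b) seq(b[1], b[2])))
  if (Tn > 0 && !identical(sort(covered), seq_len(Tn)))
    msg <- c(msg, "segmentBounds must partition the bin axis")
  if (length(msg)) msg else TRUE
})

#' Construct an EnvelopeSeries
#'
#' @param values channels x bins numeric matrix.
#' @param binMs bin width (ms), default 250.
#' @param binTimeS start time of each bin (s); defaults to a regular grid
#'   from 0.
#' @param segmentBounds list of `c(first, last)` bin ranges; defaults to one
#'   segment spanning everything.
#' @param channelIds channel labels.
#' @return An [EnvelopeSeries-class] object.
#' @export
EnvelopeSeries <- function(values, binMs = 250, binTimeS = NULL,
                           segmentBounds = NULL, channelIds = NULL) {
  Tn <- ncol(values)
  if (is.null(binTimeS)) binTimeS <- (seq_len(Tn) - 1) * binMs / 1000
  if (is.null(segmentBounds)) segmentBounds <- list(c(1L, Tn))
  segmentBounds <- lapply(segmentBounds, as.integer)
  if (is.null(channelIds)) channelIds <- sprintf("ch%02d", seq_len(nrow(values)))
  new("EnvelopeSeries", values = values, binMs = binMs, binTimeS = binTimeS,
      segmentBounds = segmentBounds, channelIds = channelIds)
}

setMethod("show", "EnvelopeSeries", function(object) {
  cat(sprintf("EnvelopeSeries: %d channels x %d bins @ %g ms (%d segment%s)\n",
              nrow(object@values), ncol(object@values), object@binMs,
              length(object@segmentBounds),
              if (length(object@segmentBounds) == 1) "" else "s"))
})

#' Labeled 30-second epochs
#'
#' Stack of fixed-length epochs cut from an [EnvelopeSeries-class]: a
#' channels x bins-per-epoch x epochs array plus one behavioral-state label
#' per epoch. Epochs are chronological and each lies inside a single
#' contiguous segment and a single labeled block.
#'
#' @slot epochs numeric array `[q, T, E]`.
#' @slot labels character, state label per epoch.
#' @slot epochStartBin integer, index of each epoch's first bin in the source
#'   series.
#' @slot epochStartS numeric, wall-clock start (s) of each epoch.
#' @slot binMs bin width (ms).
#' @slot channelIds channel labels.
#' @slot subjectTag free-text provenance tag.
#' @exportClass EpochSet
setClass("EpochSet",
  representation(epochs = "array", labels = "character",
                 epochStartBin = "integer", epochStartS = "numeric",
                 binMs = "numeric", channelIds = "character",
                 subjectTag = "character"))

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@epochs)
  if (length(d) != 3) msg <- c(msg, "epochs must be a 3-d array [q, T, E]")
  else {
    if (length(object@labels) != d[3]) msg <- c(msg, "one label per epoch required")
    if (length(object@epochStartBin) != d[3])
      msg <- c(msg, "one start bin per epoch required")
    if (length(object@epochStartS) != d[3])
      msg <- c(msg, "one start time per epoch required")
    if (length(object@channelIds) != d[1])
      msg <- c(msg, "channelIds length must match channels")
  }
  if (is.unsorted(object@epochStartS)) msg <- c(msg, "epochs must be chronological")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@epochs)
  tab <- table(object@labels)
  cat(sprintf("EpochSet: %d epochs (%d channels x %d bins @ %g ms)\n",
              d[3], d[1], d[2], object@binMs))
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

#' Ground-truth generative parameters of one behavioral state
#'
#' Per-state parameters the synthetic generator plants: channel means and
#' standard deviations, a loading matrix mapping latent factors onto
#' channels, and a Gaussian-process timescale per factor.
#'
#' @slot name state label.
#' @slot channelMean numeric `[q]`, envelope units.
#' @slot channelSd positive numeric `[q]`.
#' @slot loading numeric matrix `[q x pTrue]`.
#' @slot tausMs positive numeric `[pTrue]`, milliseconds.
#' @slot factorScale positive numeric `[pTrue]` multiplying each factor.
#' @exportClass StateSpec
setClass("StateSpec",
  representation(name = "character", channelMean = "numeric",
                 channelSd = "numeric", loading = "matrix",
                 tausMs = "numeric", factorScale = "numeric"))

setValidity("StateSpec", function(object) {
  msg <- character()
  q <- length(object@channelMean)
  if (length(object@channelSd) != q) msg <- c(msg, "channelSd length mismatch")
  if (any(object@channelSd <= 0)) msg <- c(msg, "channelSd must be positive")
  if (nrow(object@loading) != q) msg <- c(msg, "loading must have q rows")
  p <- ncol(object@loading)
  if (length(object@tausMs) != p) msg <- c(msg, "one tau per factor required")
  if (any(object@tausMs <= 0)) msg <- c(msg, "tausMs must be positive")
  if (length(object@factorScale) != p) msg <- c(msg, "one scale per factor required")
  if (any(object@factorScale <= 0)) msg <- c(msg, "factorScale must be positive")
  if (p > 0 && any(colSums(abs(object@loading)) == 0))
    msg <- c(msg, "loading must have no all-zero column")
  if (length(msg)) msg else TRUE
})

#' Construct a StateSpec
#'
#' @param name state label.
#' @param channelMean per-channel envelope mean.
#' @param channelSd per-channel envelope standard deviation (positive).
#' @param loading `q x pTrue` loading matrix.
#' @param tausMs per-factor Gaussian-process timescale (ms).
#' @param factorScale per-factor amplitude multiplier.
#' @return A [StateSpec-class] object.
#' @export
StateSpec <- function(name, channelMean, channelSd, loading, tausMs,
                      factorScale = rep(1, length(tausMs))) {
  new("StateSpec", name = name, channelMean = channelMean,
      channelSd = channelSd, loading = as.matrix(loading),
      tausMs = tausMs, factorScale = factorScale)
}

setMethod("show", "StateSpec", function(object) {
  cat(sprintf("StateSpec '%s': q=%d channels, %d latent factor(s), tau(ms)=%s\n",
              object@name, length(object@channelMean), ncol(object@loading),
              paste(signif(object@tausMs, 3), collapse = ", ")))
})

#' Blocked cross-validation plan with temporal buffer
#'
#' Assignment of chronologically ordered epochs to `nFolds` contiguous folds.
#' For each test fold, training excludes the test fold itself, the
#' `bufferFolds` temporally adjacent folds on each side, and (optionally) any
#' epoch closer than `minGapS` seconds to a test epoch.
#'
#' @slot nFolds number of folds.
#' @slot foldOfEpoch integer fold index (1-based) per epoch.
#' @slot bufferFolds folds excluded on each side of the test fold.
#' @slot minGapS extra minimum test/train gap in seconds (0 disables).
#' @slot epochStartS epoch start times used for the gap rule.
#' @slot epochS epoch duration in seconds.
#' @exportClass CVPlan
setClass("CVPlan",
  representation(nFolds = "integer", foldOfEpoch = "integer",
                 bufferFolds = "integer", minGapS = "numeric",
                 epochStartS = "numeric", epochS = "numeric"))

setValidity("CVPlan", function(object) {
  msg <- character()
  if (length(object@foldOfEpoch) != length(object@epochStartS))
    msg <- c(msg, "foldOfEpoch and epochStartS must have equal length")
  if (is.unsorted(object@foldOfEpoch))
    msg <- c(msg, "folds must be contiguous in time")
  if (!all(seq_len(object@nFolds) %in% object@foldOfEpoch))
    msg <- c(msg, "every fold must be non-empty")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CVPlan", function(object) {
  cat(sprintf("CVPlan: %d epochs in %d contiguous folds, %d-fold buffer%s\n",
              length(object@foldOfEpoch), object@nFolds, object@bufferFolds,
              if (object@minGapS > 0) sprintf(", min gap %g s", object@minGapS) else ""))
})

#' Fitted GPFA (or FA) parameters
#'
#' Observation model `y_t | x_t ~ N(C x_t + d, R)` with diagonal `R`, and,
#' for GPFA, an independent squared-exponential Gaussian-process prior per
#' latent factor with timescale `tausMs[i]` and noise floor `sigmaNSq`.
#' For a plain factor-analysis fit `tausMs` is empty.
#'
#' @slot C loading matrix `[q x p]`.
#' @slot d offset vector `[q]`.
#' @slot R diagonal observation noise variances `[q]`.
#' @slot tausMs per-factor timescale (ms); `numeric(0)` for FA.
#' @slot sigmaNSq GP kernel noise floor.
#' @slot binMs bin width the model was fit at (ms).
#' @slot fitLog per-iteration data log-likelihood.
#' @slot converged whether the EM tolerance was reached.
#' @exportClass GPFAParams
setClass("GPFAParams",
  representation(C = "matrix", d = "numeric", R = "numeric",
                 tausMs = "numeric", sigmaNSq = "numeric", binMs = "numeric",
                 fitLog = "numeric", converged = "logical"))

setValidity("GPFAParams", function(object) {
  msg <- character()
  if (length(object@d) != nrow(object@C)) msg <- c(msg, "d must have q entries")
  if (length(object@R) != nrow(object@C)) msg <- c(msg, "R must have q entries")
  if (any(object@R <= 0)) msg <- c(msg, "R entries must be positive")
  if (length(object@tausMs) && length(object@tausMs) != ncol(object@C))
    msg <- c(msg, "tausMs must have one entry per factor (or none for FA)")
  if (any(object@tausMs <= 0)) msg <- c(msg, "tausMs must be positive")
  if (length(object@fitLog) > 1 &&
      any(diff(object@fitLog) < -1e-6 * (1 + abs(object@fitLog[-1]))))
    msg <- c(msg, "fitLog must be non-decreasing (EM monotonicity)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GPFAParams", function(object) {
  kind <- if (length(object@tausMs)) "GPFA" else "FA"
  cat(sprintf("%s fit: q=%d channels, p=%d factors, %d EM iterations%s\n",
              kind, nrow(object@C), ncol(object@C), length(object@fitLog),
              if (isTRUE(object@converged)) "" else " (not converged)"))
  if (length(object@tausMs))
    cat("  tau (ms):", paste(signif(sort(object@tausMs), 3), collapse = ", "), "\n")
})

#' Posterior latent trajectories
#'
#' Per-epoch posterior means `E[x | y]` of the latent factors, either raw
#' (`ortho = FALSE`) or orthonormalized through the SVD of the loading matrix
#' (`ortho = TRUE`), in which case `U` holds the orthonormal spatial factors
#' and `Ddiag` the singular values ordering them by covariance explained.
#'
#' @slot paths numeric array `[p, T, E]`.
#' @slot ortho logical flag.
#' @slot U orthonormal loading `[q x p]` when `ortho`, else 0 x 0.
#' @slot Ddiag singular values when `ortho`, else `numeric(0)`.
#' @slot tausMs per-factor timescale carried from the fit (raw order).
#' @slot binMs bin width (ms).
#' @exportClass LatentTrajectories
setClass("LatentTrajectories",
  representation(paths = "array", ortho = "logical", U = "matrix",
                 Ddiag = "numeric", tausMs = "numeric", binMs = "numeric"))

setValidity("LatentTrajectories", function(object) {
  msg <- character()
  if (length(dim(object@paths)) != 3) msg <- c(msg, "paths must be [p, T, E]")
  if (object@ortho) {
    if (!length(object@Ddiag)) msg <- c(msg, "ortho trajectories need Ddiag")
    if (length(object@Ddiag) > 1 && is.unsorted(rev(object@Ddiag)))
      msg <- c(msg, "Ddiag must be ordered decreasing")
    if (ncol(object@U)) {
      g <- crossprod(object@U)
      if (max(abs(g - diag(ncol(object@U)))) > 1e-8)
        msg <- c(msg, "U must have orthonormal columns")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "LatentTrajectories", function(object) {
  d <- dim(object@paths)
  cat(sprintf("LatentTrajectories: %d epochs x %d factors x %d bins (%s)\n",
              d[3], d[1], d[2],
              if (object@ortho) "orthonormalized" else "raw"))
})
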