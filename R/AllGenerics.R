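#' Channel labels
#' @param x a RawRecording, EnvelopeSeries or EpochSet.
#' @return character vector of channel labels.
#' @export
setGeneric("channelIds", function(x) standardGeneric("channelIds"))

#' @rdname channelIds
setMethod("channelIds", "RawRecording", function(x) x@channelIds)
#' @rdname channelIds
setMethod("channelIds", "EnvelopeSeries", function(x) x@channelIds)
#' @rdname channelIds
setMethod("channelIds", "EpochSet", function(x) x@channelIds)

#' Bin width in milliseconds
#' @param x an EnvelopeSeries, EpochSet, GPFAParams or LatentTrajectories.
#' @return bin width (ms).
#' @export
setGeneric("binMs", function(x) standardGeneric("binMs"))

#' @rdname binMs
setMethod("binMs", "EnvelopeSeries", function(x) x@binMs)
#' @rdname binMs
setMethod("binMs", "EpochSet", function(x) x@binMs)
#' @rdname binMs
setMethod("binMs", "GPFAParams", function(x) x@binMs)
#' @rdname binMs
setMethod("binMs", "LatentTrajectories", function(x) x@binMs)

#' Raw sample matrix of a recording
#' @param x a RawRecording.
#' @return channels x samples matrix.
#' @export
rawSamples <- function(x) x@samples

#' Sampling rate of a recording (Hz)
#' @param x a RawRecording.
#' @return sampling rate in Hz.
#' @export
samplingRate <- function(x) x@fsHz

#' Envelope value matrix
#' @param x an EnvelopeSeries.
#' @return channels x bins matrix.
#' @export
envelopeValues <- function(x) x@values

#' Contiguous-segment bin ranges
#' @param x an EnvelopeSeries.
#' @return list of `c(first, last)` bin index pairs.
#' @export
segmentBounds <- function(x) x@segmentBounds

#' Bin start times (seconds)
#' @param x an EnvelopeSeries.
#' @return numeric vector of bin start times.
#' @export
binTimes <- function(x) x@binTimeS

#' Epoch data array
#' @param x an EpochSet.
#' @return numeric array `[q, T, E]`.
#' @export
epochArray <- function(x) x@epochs

#' Epoch state labels
#' @param x an EpochSet.
#' @return character vector, one label per epoch.
#' @export
epochLabels <- function(x) x@labels

#' Number of epochs
#' @param x an EpochSet.
#' @return integer epoch count.
#' @export
nEpochs <- function(x) dim(x@epochs)[3]

#' Epoch start times (seconds)
#' @param x an EpochSet.
#' @return numeric vector of epoch start times.
#' @export
epochStartTimes <- function(x) x@epochStartS

#' Fold assignment of a CV plan
#' @param plan a CVPlan.
#' @return integer fold index per epoch.
#' @export
foldOfEpoch <- function(plan) plan@foldOfEpoch

#' Number of folds of a CV plan
#' @param plan a CVPlan.
#' @return integer number of folds.
#' @export
nFolds <- function(plan) plan@nFolds

#' Loading matrix of a fitted model
#' @param x a GPFAParams.
#' @return `q x p` loading matrix.
#' @export
loadingMatrix <- function(x) x@C

#' Channel offsets of a fitted model
#' @param x a GPFAParams.
#' @return numeric offset vector `d`.
#' @export
channelOffsets <- function(x) x@d

#' Diagonal observation-noise variances
#' @param x a GPFAParams.
#' @return numeric vector of per-channel noise variances.
#' @export
noiseVariances <- function(x) x@R

#' Fitted per-factor timescales (ms)
#' @param x a GPFAParams or LatentTrajectories.
#' @return numeric vector of timescales; empty for a plain FA fit.
#' @export
timescales <- function(x) x@tausMs

#' Per-iteration log-likelihood trace of an EM fit
#' @param x a GPFAParams.
#' @return numeric vector of data log-likelihoods.
#' @export
fitLog <- function(x) x@fitLog

#' Latent trajectory array
#' @param x a LatentTrajectories.
#' @return numeric array `[p, T, E]` of posterior means.
#' @export
latentPaths <- function(x) x@paths
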