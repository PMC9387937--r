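# Plain-text serialization: behavioral-state label blocks, envelopes, and
# per-fold decoding results.

#' Read 5-minute behavioral-state block labels from TSV
#'
#' @param path TSV file with columns `start_s`, `end_s`, `state`.
#' @return data.frame of validated, non-overlapping blocks sorted by start
#'   time (possibly zero rows for an empty file).
#' @export
readStateLabels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s", "state")
  if (!all(need %in% names(df)))
    stop("label file must have columns start_s, end_s, state")
  df <- df[order(df$start_s), need]
  if (nrow(df) > 1 &&
      any(df$start_s[-1] < df$end_s[-nrow(df)] - 1e-9))
    stop("label blocks overlap")
  if (any(df$end_s <= df$start_s)) stop("block durations must be positive")
  df
}

#' Write behavioral-state blocks to TSV
#' @param blocks data.frame (`start_s`, `end_s`, `state`).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeStateLabels <- function(blocks, path) {
  utils::write.table(blocks[, c("start_s", "end_s", "state")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an EnvelopeSeries to TSV
#'
#' One row per bin: `time_s`, `segment`, then one column per channel.
#'
#' @param env an [EnvelopeSeries-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeEnvelopeTSV <- function(env, path) {
  segId <- integer(ncol(env@values))
  for (i in seq_along(env@segmentBounds)) {
    b <- env@segmentBounds[[i]]
    segId[seq(b[1], b[2])] <- i
  }
  df <- data.frame(time_s = env@binTimeS, segment = segId,
                   t(env@values), check.names = FALSE)
  names(df)[-(1:2)] <- env@channelIds
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an EnvelopeSeries from TSV
#' @param path a file written by [writeEnvelopeTSV()].
#' @param binMs bin width (ms), default 250.
#' @return An [EnvelopeSeries-class].
#' @export
readEnvelopeTSV <- function(path, binMs = 250) {
  df <- utils::read.delim(path, check.names = FALSE)
  segId <- df$segment
  bounds <- lapply(unique(segId), function(s) {
    idx <- which(segId == s)
    c(min(idx), max(idx))
  })
  vals <- t(as.matrix(df[, setdiff(names(df), c("time_s", "segment")),
                         drop = FALSE]))
  cid <- rownames(vals)
  dimnames(vals) <- NULL
  EnvelopeSeries(vals, binMs = binMs, binTimeS = df$time_s,
                 segmentBounds = bounds, channelIds = cid)
}

#' Write per-fold cross-validation results to TSV
#' @param res a `cvAccuracy` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFoldResults <- function(res, path) {
  utils::write.table(res$folds, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
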