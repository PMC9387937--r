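# Blocked cross-validation with a temporal buffer, class balancing, and the
# binomial finite-sample chance level.

#' Build a blocked cross-validation plan with a temporal buffer
#'
#' Chronologically ordered epochs are split into `k` contiguous folds of
#' near-equal size (sizes differ by at most 1). For each test fold, the
#' `bufferFolds` temporally adjacent folds on each side are excluded from
#' training so test and training data are well separated in time; an
#' optional `minGapS` additionally excludes any training epoch closer than
#' that many seconds to a test epoch.
#'
#' @param es an [EpochSet-class].
#' @param k number of folds (default 7).
#' @param bufferFolds folds excluded on each side of the test fold
#'   (default 1).
#' @param minGapS extra minimum test/train gap in seconds (default 0: the
#'   fold buffer alone enforces separation).
#' @return A [CVPlan-class].
#' @export
makeCVPlan <- function(es, k = 7, bufferFolds = 1, minGapS = 0) {
  E <- nEpochs(es)
  if (E < 2 * k) stop("too few epochs for the requested number of folds")
  sizes <- rep(E %/% k, k)
  if (E %% k) sizes[seq_len(E %% k)] <- sizes[seq_len(E %% k)] + 1L
  fold <- rep(seq_len(k), times = sizes)
  d <- dim(es@epochs)
  new("CVPlan", nFolds = as.integer(k), foldOfEpoch = as.integer(fold),
      bufferFolds = as.integer(bufferFolds), minGapS = minGapS,
      epochStartS = es@epochStartS, epochS = d[2] * es@binMs / 1000)
}

#' Test-epoch indices of a fold
#' @param plan a [CVPlan-class].
#' @param fold fold index in `1..nFolds(plan)`.
#' @return integer vector of epoch indices.
#' @export
testIndices <- function(plan, fold) which(plan@foldOfEpoch == fold)

#' Training-epoch indices of a fold (buffer applied)
#'
#' Excludes the test fold, the buffered adjacent folds, and (when
#' `minGapS > 0`) any epoch within that gap of a test epoch.
#'
#' @inheritParams testIndices
#' @return integer vector of epoch indices.
#' @export
trainIndices <- function(plan, fold) {
  excl <- seq(fold - plan@bufferFolds, fold + plan@bufferFolds)
  tr <- which(!(plan@foldOfEpoch %in% excl))
  if (plan@minGapS > 0 && length(tr)) {
    te <- testIndices(plan, fold)
    gapOK <- vapply(tr, function(i) {
      gaps <- abs(plan@epochStartS[i] - plan@epochStartS[te]) - plan@epochS
      min(gaps) >= plan@minGapS
    }, logical(1))
    tr <- tr[gapOK]
  }
  tr
}

#' Class-balance an index set by uniform subsampling
#'
#' Subsamples without replacement so every class count equals the minimum
#' class count within the set; deterministic given `seed`.
#'
#' @param indices integer epoch indices to balance.
#' @param labels label vector for the full epoch set.
#' @param seed integer seed for the subsampling.
#' @param classes class set that must all be present; defaults to all labels
#'   seen in `labels`.
#' @return integer vector of balanced indices (chronological order).
#' @export
balanceClasses <- function(indices, labels, seed = 1,
                           classes = sort(unique(labels))) {
  sub <- labels[indices]
  missing <- setdiff(classes, sub)
  if (length(missing))
    stop(sprintf("class absent from the index set: %s",
                 paste(missing, collapse = ", ")))
  nMin <- min(table(factor(sub, levels = classes)))
  set.seed(seed)
  keep <- unlist(lapply(classes, function(cl) {
    i <- indices[sub == cl]
    if (length(i) > nMin) sort(sample(i, nMin)) else i
  }))
  sort(keep)
}

#' Binomial finite-sample chance level
#'
#' The accuracy threshold that cannot be exceeded by guessing at significance
#' level `alpha` given a finite number of balanced trials: the smallest `k*`
#' with `BinomCDF(k*; nTrials, 1/nClasses) >= 1 - alpha`, expressed as
#' `100 k*/nTrials` percent.
#'
#' @param nTrials number of (balanced) classified trials.
#' @param nClasses number of classes.
#' @param alpha significance level in (0, 1), default 0.05.
#' @return list with `nTrials`, `nClasses`, `alpha`, `levelPct` (exact
#'   percent) and `levelPctRounded` (nearest integer percent).
#' @examples
#' chanceLevel(320, 4)$levelPctRounded  # 29
#' chanceLevel(450, 3)$levelPctRounded  # 37
#' @export
chanceLevel <- function(nTrials, nClasses, alpha = 0.05) {
  if (nTrials < 1 || nClasses < 2) stop("need nTrials >= 1 and nClasses >= 2")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  kStar <- stats::qbinom(1 - alpha, nTrials, 1 / nClasses)
  pct <- 100 * kStar / nTrials
  list(nTrials = nTrials, nClasses = nClasses, alpha = alpha,
       levelPct = pct, levelPctRounded = round(pct))
}

#' Serialize a CV plan to JSON
#' @param plan a [CVPlan-class].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
cvPlanToJSON <- function(plan, path = NULL) {
  js <- jsonlite::toJSON(list(
    nFolds = plan@nFolds, foldOfEpoch = plan@foldOfEpoch,
    bufferFolds = plan@bufferFolds, minGapS = plan@minGapS,
    epochStartS = plan@epochStartS, epochS = plan@epochS), digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' Restore a CV plan from JSON
#' @param x a JSON string or file path from [cvPlanToJSON()].
#' @return A [CVPlan-class].
#' @export
cvPlanFromJSON <- function(x) {
  l <- jsonlite::fromJSON(x)
  new("CVPlan", nFolds = as.integer(l$nFolds),
      foldOfEpoch = as.integer(l$foldOfEpoch),
      bufferFolds = as.integer(l$bufferFolds), minGapS = l$minGapS,
      epochStartS = l$epochStartS, epochS = l$epochS)
}
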