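# End-to-end orchestration: synthesize or load an envelope dataset, derive
# the feature families, run buffered blocked cross-validated decoding, and
# assemble a report with chance levels attached.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build an experiment configuration
#'
#' @param source either `list(type = "synthetic", specs = ..., schedule =
#'   ...)` (both optional; defaults are [defaultStateSpecs()] and a 7-cycle
#'   [makeSchedule()]) or `list(type = "files", envelope = <TSV path>,
#'   labels = <TSV path>)`.
#' @param families feature families to decode, a subset of `"mean"`,
#'   `"variance"`, `"covariance"`, `"slow"`, `"fast"`, `"gpfa"`.
#' @param k folds (default 7); `bufferFolds` buffer (default 1).
#' @param bufferFolds folds excluded each side of the test fold.
#' @param alpha chance-level significance (default 0.05).
#' @param epochS epoch length in seconds (default 30).
#' @param zscore apply 5-minute z-scoring for the families that require it
#'   (default `TRUE`; setting `FALSE` while requesting such a family is a
#'   configuration error).
#' @param gpfa list of GPFA settings: `p` (factors, default 4), `maxIter`,
#'   `tol`.
#' @param seed master integer seed.
#' @return a validated config list.
#' @export
experimentConfig <- function(source = list(type = "synthetic"),
                             families = c("mean", "variance", "covariance",
                                          "slow", "fast"),
                             k = 7, bufferFolds = 1, alpha = 0.05,
                             epochS = 30, zscore = TRUE,
                             gpfa = list(p = 4, maxIter = 100, tol = 1e-5),
                             seed = 1) {
  known <- c("mean", "variance", "covariance", "slow", "fast", "gpfa")
  if (!all(families %in% known))
    stop("unknown feature family: ", paste(setdiff(families, known),
                                           collapse = ", "))
  needZ <- intersect(families, c("covariance", "slow", "fast", "gpfa"))
  if (length(needZ) && !zscore)
    stop("families ", paste(needZ, collapse = ", "),
         " require 5-minute z-scoring")
  gpfa <- utils::modifyList(list(p = 4, maxIter = 100, tol = 1e-5), gpfa)
  list(source = source, families = families, k = k,
       bufferFolds = bufferFolds, alpha = alpha, epochS = epochS,
       zscore = zscore, gpfa = gpfa, seed = seed)
}

# CV plan over an explicit epoch-time vector (used when band splitting drops
# epochs and the main plan no longer aligns).
planFromTimes <- function(startS, epochS, k, bufferFolds, minGapS = 0) {
  E <- length(startS)
  if (E < 2 * k) stop("too few epochs for the requested number of folds")
  sizes <- rep(E %/% k, k)
  if (E %% k) sizes[seq_len(E %% k)] <- sizes[seq_len(E %% k)] + 1L
  new("CVPlan", nFolds = as.integer(k),
      foldOfEpoch = as.integer(rep(seq_len(k), times = sizes)),
      bufferFolds = as.integer(bufferFolds), minGapS = minGapS,
      epochStartS = startS, epochS = epochS)
}

#' Run an end-to-end decoding experiment
#'
#' Executes the requested feature families with the z-scoring each requires
#' (mean/variance: none; covariance, slow, fast, GPFA: per 5-minute block),
#' under one blocked buffered cross-validation plan, and attaches the
#' binomial finite-sample chance level to every accuracy.
#'
#' @param config a list from [experimentConfig()].
#' @return list of class `stateReport`: `accuracies` (named `cvAccuracy`
#'   per family), `chance`, `plan`, `nEpochs`, `classes`, `gpfaCurves`
#'   (when requested), `config`, `packageVersion`.
#' @export
runExperiment <- function(config) {
  cfg <- do.call(experimentConfig, config[setdiff(names(config), "")])
  if (cfg$source$type == "synthetic") {
    specs <- cfg$source$specs %||% defaultStateSpecs()
    schedule <- cfg$source$schedule %||% makeSchedule(names(specs), 7)
    gen <- generateEnvelopeDataset(specs, schedule, seed = cfg$seed)
    env <- gen$env; blocks <- gen$labels
  } else if (cfg$source$type == "files") {
    env <- readEnvelopeTSV(cfg$source$envelope)
    blocks <- readStateLabels(cfg$source$labels)
    if (!nrow(blocks)) stop("empty label schedule: nothing to decode")
  } else stop("unknown source type")

  es <- epochEnvelope(env, blocks, epochS = cfg$epochS)
  plan <- makeCVPlan(es, k = cfg$k, bufferFolds = cfg$bufferFolds)
  labs <- epochLabels(es)
  counts <- table(labs)
  chance <- chanceLevel(min(counts) * length(counts), length(counts),
                        alpha = cfg$alpha)

  envZ <- if (cfg$zscore) zscoreSegments(env, blocks = blocks) else NULL
  esZ <- if (cfg$zscore) epochEnvelope(envZ, blocks, epochS = cfg$epochS)
         else NULL

  acc <- list(); curves <- NULL
  q <- length(channelIds(es))
  if (any(c("mean", "variance") %in% cfg$families)) {
    mv <- epochMeanVar(es)
    if ("mean" %in% cfg$families)
      acc$mean <- trainEvalSVM(mv[, seq_len(q), drop = FALSE], labs, plan,
                               seed = cfg$seed)
    if ("variance" %in% cfg$families)
      acc$variance <- trainEvalSVM(mv[, q + seq_len(q), drop = FALSE], labs,
                                   plan, seed = cfg$seed)
  }
  if ("covariance" %in% cfg$families)
    acc$covariance <- trainEvalMDM(epochCovariance(esZ), epochLabels(esZ),
                                   plan, seed = cfg$seed)
  if (any(c("slow", "fast") %in% cfg$families)) {
    bs <- bandsplitEnvelope(envZ, blocks, epochS = cfg$epochS)
    bsPlan <- if (length(bs$labels) == nEpochs(es)) plan
      else planFromTimes(bs$epochStartS, cfg$epochS, cfg$k, cfg$bufferFolds)
    if ("slow" %in% cfg$families)
      acc$slow <- trainEvalSVM(bs$slow, bs$labels, bsPlan, seed = cfg$seed)
    if ("fast" %in% cfg$families)
      acc$fast <- trainEvalSVM(bs$fast, bs$labels, bsPlan, seed = cfg$seed)
  }
  if ("gpfa" %in% cfg$families) {
    folds <- gpfaFoldLatents(esZ, plan = plan, p = cfg$gpfa$p,
                             seed = cfg$seed, maxIter = cfg$gpfa$maxIter,
                             tol = cfg$gpfa$tol)
    slow <- factorDecodingCurve(folds, "slow_first")
    fast <- factorDecodingCurve(folds, "fast_first")
    lda <- factorDecodingCurve(folds, "slow_first", sharedCovariance = TRUE)
    curves <- list(slowFirst = slow, fastFirst = fast, ldaControl = lda,
                   singleFactor = singleFactorDecoding(folds))
    full <- slow[nrow(slow), ]
    acc$gpfa <- structure(list(
      folds = data.frame(fold = NA, nTrain = NA, nTest = NA,
                         accuracy = full$accuracy),
      meanAccuracy = full$accuracy, seAccuracy = full$se),
      class = "cvAccuracy")
  }
  structure(list(accuracies = acc, chance = chance, plan = plan,
                 nEpochs = nEpochs(es), classes = names(counts),
                 gpfaCurves = curves, config = cfg,
                 packageVersion = as.character(utils::packageVersion("gammastate"))),
            class = "stateReport")
}

#' @export
print.stateReport <- function(x, ...) {
  cat(sprintf("Behavioral-state decoding report: %d epochs, %d classes (%s)\n",
              x$nEpochs, length(x$classes), paste(x$classes, collapse = ", ")))
  cat(sprintf("Chance level: %d%% (binomial, n=%d, alpha=%g)\n",
              x$chance$levelPctRounded, x$chance$nTrials, x$chance$alpha))
  for (fam in names(x$accuracies)) {
    a <- x$accuracies[[fam]]
    cat(sprintf("  %-10s %5.1f%% +/- %.1f%%\n", fam, 100 * a$meanAccuracy,
                100 * ifelse(is.na(a$seAccuracy), 0, a$seAccuracy)))
  }
  invisible(x)
}
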