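# Decoder families: linear SVM on feature vectors, Euclidean
# minimum-distance-to-mean on covariance matrices, and the block-structured
# constrained Gaussian (QDA/LDA) over vectorized latent trajectories.

foldResult <- function(df) {
  structure(list(folds = df, meanAccuracy = mean(df$accuracy),
                 seAccuracy = stats::sd(df$accuracy) / sqrt(nrow(df))),
            class = "cvAccuracy")
}

#' @export
print.cvAccuracy <- function(x, ...) {
  cat(sprintf("Cross-validated accuracy: %.1f%% +/- %.1f%% over %d folds\n",
              100 * x$meanAccuracy, 100 * ifelse(is.na(x$seAccuracy), 0,
                                                 x$seAccuracy),
              nrow(x$folds)))
  invisible(x)
}

# Balanced train/test index pair for one fold; seeds derived deterministically.
balancedFold <- function(plan, fold, labels, seed) {
  tr <- balanceClasses(trainIndices(plan, fold), labels, seed = seed + fold)
  te <- balanceClasses(testIndices(plan, fold), labels,
                       seed = seed + fold + 10000L)
  list(train = tr, test = te)
}

#' Cross-validated linear SVM decoding
#'
#' Per fold: balance the training and test sets, standardize features using
#' training-set statistics, fit a multi-class linear-kernel SVM (one-vs-one
#' vote aggregation), and report balanced-test accuracy.
#'
#' @param features numeric matrix `[E x d]` of epoch features.
#' @param labels state label per epoch.
#' @param plan a [CVPlan-class].
#' @param seed integer seed (class balancing).
#' @param cost SVM regularization constant (default 1).
#' @param standardize standardize features per fold from the training set
#'   (default `TRUE`).
#' @return `cvAccuracy` object: per-fold data.frame (`fold`, `nTrain`,
#'   `nTest`, `accuracy`) plus mean and standard error.
#' @export
trainEvalSVM <- function(features, labels, plan, seed = 1, cost = 1,
                         standardize = TRUE) {
  stopifnot(all(is.finite(features)))
  res <- lapply(seq_len(plan@nFolds), function(f) {
    sets <- balancedFold(plan, f, labels, seed)
    xtr <- features[sets$train, , drop = FALSE]
    xte <- features[sets$test, , drop = FALSE]
    ytr <- factor(labels[sets$train])
    if (nlevels(ytr) < 2) stop("degenerate single-class training set")
    if (standardize) {
      mu <- colMeans(xtr)
      sg <- apply(xtr, 2, stats::sd)
      sg[sg == 0] <- 1
      xtr <- scale(xtr, mu, sg)
      xte <- scale(xte, mu, sg)
    }
    fit <- e1071::svm(xtr, ytr, kernel = "linear", cost = cost, scale = FALSE)
    pred <- as.character(stats::predict(fit, xte))
    data.frame(fold = f, nTrain = length(sets$train),
               nTest = length(sets$test),
               accuracy = mean(pred == labels[sets$test]))
  })
  foldResult(do.call(rbind, res))
}

#' Fit a minimum-distance-to-mean covariance classifier
#'
#' The class representative is the Euclidean (arithmetic) mean of that
#' class's training covariance matrices.
#'
#' @param covs numeric array `[q, q, E]` of covariance matrices.
#' @param labels label per matrix.
#' @return list with `classes` (canonical order) and `classMeans`.
#' @export
mdmFit <- function(covs, labels) {
  classes <- sort(unique(labels))
  means <- lapply(classes, function(cl) {
    idx <- which(labels == cl)
    m <- apply(covs[, , idx, drop = FALSE], c(1, 2), mean)
    (m + t(m)) / 2
  })
  names(means) <- classes
  list(classes = classes, classMeans = means)
}

#' Predict with a minimum-distance-to-mean model
#'
#' Assigns the class whose mean matrix is nearest in Frobenius distance;
#' ties break to the first class in canonical order (with a message).
#'
#' @param model a fit from [mdmFit()].
#' @param S a `q x q` covariance matrix.
#' @return list with `label` and named `distances`.
#' @export
mdmPredict <- function(model, S) {
  d <- vapply(model$classMeans, function(M) sqrt(sum((S - M)^2)), numeric(1))
  if (sum(d == min(d)) > 1) message("MDM distance tie; first class chosen")
  list(label = model$classes[which.min(d)], distances = d)
}

#' Cross-validated MDM decoding of covariance matrices
#'
#' @param covs numeric array `[q, q, E]`.
#' @param labels label per epoch.
#' @param plan a [CVPlan-class].
#' @param seed integer seed (class balancing).
#' @return `cvAccuracy` object as in [trainEvalSVM()].
#' @export
trainEvalMDM <- function(covs, labels, plan, seed = 1) {
  res <- lapply(seq_len(plan@nFolds), function(f) {
    sets <- balancedFold(plan, f, labels, seed)
    model <- mdmFit(covs[, , sets$train, drop = FALSE], labels[sets$train])
    pred <- vapply(sets$test, function(i)
      mdmPredict(model, covs[, , i])$label, character(1))
    data.frame(fold = f, nTrain = length(sets$train),
               nTest = length(sets$test),
               accuracy = mean(pred == labels[sets$test]))
  })
  foldResult(do.call(rbind, res))
}

#' Fit the block-structured constrained Gaussian classifier
#'
#' For each class, the latent-bin mean `mu_c` (static across time) and the
#' `p x p` covariance `Sigma_c` of all latent bins pooled across that
#' class's epochs. The implied model on a vectorized `p x T` epoch is a
#' `pT`-dimensional Gaussian with the mean tiled `T` times and `Sigma_c`
#' repeated along the block diagonal (time points independent). With
#' `sharedCovariance = TRUE` a single pooled covariance replaces all
#' `Sigma_c` (the LDA control).
#'
#' @param trajs a [LatentTrajectories-class] or `[p, T, E]` array.
#' @param labels label per epoch.
#' @param sharedCovariance use one pooled covariance (default `FALSE`).
#' @param ridge relative ridge added when a class covariance is singular
#'   (default 1e-6, scaled by `trace/p`).
#' @return list with `classes`, `mu` (list of `p` vectors), `Sigma` (list of
#'   `p x p` matrices), `shared`, `p`, `T`.
#' @export
constrainedGaussianFit <- function(trajs, labels, sharedCovariance = FALSE,
                                   ridge = 1e-6) {
  a <- if (is(trajs, "LatentTrajectories")) trajs@paths else trajs
  d <- dim(a)
  classes <- sort(unique(labels))
  mu <- list(); Sig <- list(); nBins <- numeric()
  for (cl in classes) {
    x <- flattenEpochs(a[, , labels == cl, drop = FALSE])
    mu[[cl]] <- rowMeans(x)
    Sig[[cl]] <- stats::cov(t(x))
    nBins[cl] <- ncol(x)
  }
  if (sharedCovariance) {
    pooled <- Reduce(`+`, Map(function(S, n) S * (n - 1), Sig, nBins)) /
      (sum(nBins) - length(classes))
    Sig <- lapply(Sig, function(S) pooled)
  }
  Sig <- lapply(Sig, function(S) {
    S <- (S + t(S)) / 2
    ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
    if (!ok) {
      message("singular class covariance; ridge regularization applied")
      S <- S + diag(ridge * sum(diag(S)) / nrow(S) + 1e-12, nrow(S))
    }
    S
  })
  list(classes = classes, mu = mu, Sigma = Sig, shared = sharedCovariance,
       p = d[1], T = d[2])
}

#' Score and classify one latent epoch under the constrained Gaussian
#'
#' The per-class score sums the `N(x_t; mu_c, Sigma_c)` log-density over the
#' epoch's bins (plus a uniform log prior), which equals the log-density of
#' the explicit `pT`-dimensional block-diagonal Gaussian. Ties break to the
#' first class.
#'
#' @param model a fit from [constrainedGaussianFit()].
#' @param epochTraj numeric `p x T` latent trajectory.
#' @return list with `label` and named `scores` (per-class log-scores).
#' @export
constrainedGaussianPredict <- function(model, epochTraj) {
  x <- matrix(epochTraj, nrow = model$p)
  Tn <- ncol(x)
  logPrior <- -log(length(model$classes))
  scores <- vapply(model$classes, function(cl) {
    L <- chol(model$Sigma[[cl]])
    xc <- x - model$mu[[cl]]
    z <- backsolve(L, xc, transpose = TRUE)
    -0.5 * (Tn * (model$p * log(2 * pi) + 2 * sum(log(diag(L)))) +
              sum(z^2)) + logPrior
  }, numeric(1))
  list(label = model$classes[which.max(scores)], scores = scores)
}

#' Cross-validated constrained Gaussian decoding given per-fold latents
#'
#' Helper for decoding latent trajectories that were inferred separately for
#' each fold: fits on the training epochs and scores the test epochs.
#'
#' @param trainTrajs `[p, T, Etr]` array of training trajectories.
#' @param trainLabels labels for the training epochs.
#' @param testTrajs `[p, T, Ete]` array of test trajectories.
#' @param testLabels labels for the test epochs.
#' @param sharedCovariance LDA control flag.
#' @return accuracy on the test epochs.
#' @export
evalConstrainedGaussian <- function(trainTrajs, trainLabels, testTrajs,
                                    testLabels, sharedCovariance = FALSE) {
  model <- constrainedGaussianFit(trainTrajs, trainLabels,
                                  sharedCovariance = sharedCovariance)
  pred <- vapply(seq_len(dim(testTrajs)[3]), function(e)
    constrainedGaussianPredict(model, testTrajs[, , e])$label, character(1))
  mean(pred == testLabels)
}
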