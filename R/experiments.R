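## Simulation experiment harnesses: balanced training/test generation,
## classifier evaluation (accuracy, row-normalized confusion matrix,
## one-vs-rest ROC), predictor error evaluation, and the mixed-mechanism
## robustness test. All entry points accept a scale factor that multiplies
## every N proportionally for fast runs.

#' Fixture background for simulation studies
#'
#' Convenience wrapper chaining [synthesizeBackgroundFits()],
#' [simulateSingleCopySet()] and [backgroundSummaries()]: a background set of
#' \code{nGenes} six-tissue single-copy expression vectors simulated from the
#' synthetic Brownian-motion fit pool. Used whenever no empirical single-copy
#' table is supplied; the standard size is 10,000 genes.
#'
#' @param nGenes background size.
#' @param m number of tissues.
#' @param seed integer seed.
#' @return a [BackgroundDistributions-class].
#' @export
fixtureBackground <- function(nGenes = 10000L, m = 6L, seed) {
  fits <- synthesizeBackgroundFits(nGenes, seed = seed)
  backgroundSummaries(simulateSingleCopySet(fits, nGenes, m, seed = seed))
}

.generateLabeled <- function(nPerClass, m, background, ranges, tpcPool,
                             seed, stream) {
  sets <- lapply(retentionClasses(), function(cl)
    drawScenarios(cl, n = nPerClass, m = m, ranges = ranges,
                  tpcPool = tpcPool,
                  seed = childSeed(seed, paste0(stream, ".", cl))))
  sc <- do.call(bindScenarios, sets)
  tr <- sampleExpressionTriplets(sc, seed = childSeed(seed, stream))
  x <- assembleFeatures(tr, tpcTimes(sc), background)
  new("LabeledDataset", features = x, scenarios = sc)
}

#' Generate a balanced training set
#'
#' Draws \code{nPerClass} scenarios under each of the five retention classes
#' (default 10,000 each, N = 50,000 total), simulates one expression triplet
#' per scenario, and assembles the feature matrix against the supplied
#' background. The full truth (class and per-tissue parameters) is recorded.
#'
#' @param nPerClass observations per class.
#' @param m number of tissues.
#' @param background a [BackgroundDistributions-class].
#' @param ranges parameter ranges, see [parameterRanges()].
#' @param tpcPool optional pool of scaled duplication times (see
#'   [drawScenarios()]).
#' @param scale factor multiplying every per-class count (for reduced-size
#'   runs); counts are rounded and floored at 1.
#' @param seed integer seed.
#' @return a [LabeledDataset-class].
#' @export
generateTrainingSet <- function(nPerClass = 10000L, m = 6L, background,
                                ranges = parameterRanges(), tpcPool = NULL,
                                scale = 1, seed) {
  nPerClass <- max(1L, as.integer(round(nPerClass * scale)))
  .generateLabeled(nPerClass, m, background, ranges, tpcPool, seed,
                   "train")
}

#' Generate a balanced test set
#'
#' As [generateTrainingSet()] but with 1,000 observations per class by
#' default (N = 5,000) and an independent random stream, so that a shared
#' master seed never reuses training randomness. Restricted evolutionary
#' regimes (e.g. alpha in [1, 10] with sigma2 in [100, 1000]) are expressed
#' through \code{ranges}.
#'
#' @inheritParams generateTrainingSet
#' @return a [LabeledDataset-class].
#' @export
generateTestSet <- function(nPerClass = 1000L, m = 6L, background,
                            ranges = parameterRanges(), tpcPool = NULL,
                            scale = 1, seed) {
  nPerClass <- max(1L, as.integer(round(nPerClass * scale)))
  .generateLabeled(nPerClass, m, background, ranges, tpcPool, seed, "test")
}

#' Evaluate a classifier on a labeled test set
#'
#' @param model a classifier [CloudModel-class].
#' @param test a [LabeledDataset-class] (or feature matrix, with
#'   \code{truth} labels supplied).
#' @param truth true class labels (optional for a LabeledDataset).
#' @param roc compute one-vs-rest ROC curves (via pROC) and their
#'   macro-averaged AUC.
#' @return list with \code{accuracy} (fraction of argmax calls matching
#'   truth), \code{confusion} (5 x 5 row-normalized matrix, true class in
#'   rows), \code{calls}, and when requested \code{roc} (per-class pROC
#'   curves) and \code{macroAUC}.
#' @export
evaluateClassifier <- function(model, test, truth = NULL, roc = FALSE) {
  if (is(test, "LabeledDataset") && is.null(truth))
    truth <- retentionClass(test)
  res <- classifyDuplicates(model, test)
  lv <- retentionClasses()
  truthF <- factor(truth, levels = lv)
  callF <- factor(res$labels, levels = lv)
  counts <- table(truth = truthF, call = callF)
  confusion <- sweep(unclass(counts), 1L, pmax(1L, rowSums(counts)), "/")
  out <- list(accuracy = mean(res$labels == as.character(truth)),
              confusion = confusion, calls = res$labels)
  if (roc) {
    curves <- lapply(lv, function(cl)
      pROC::roc(response = truthF == cl,
                predictor = res$probabilities[, cl],
                levels = c(FALSE, TRUE), direction = "<", quiet = TRUE))
    names(curves) <- lv
    out$roc <- curves
    out$macroAUC <- mean(vapply(curves, function(r) as.numeric(pROC::auc(r)),
                                numeric(1)))
  }
  out
}

#' Evaluate a parameter predictor on a labeled test set
#'
#' For each observation and each of the five parameter types, the error
#' (predicted minus true, on the training scale: theta raw, alpha and sigma2
#' in log10) is averaged across the m tissues. Errors are summarized per
#' parameter and true class; the per-parameter mean errors are tested
#' against zero with two-sided one-sample t-tests, Bonferroni-corrected
#' across the 5 parameters x 5 classes grid.
#'
#' @param model a predictor [CloudModel-class].
#' @param test a [LabeledDataset-class].
#' @return list with \code{errors} (long data.frame: class, parameter,
#'   meanError per observation), \code{summary} (per class x parameter mean,
#'   sd, n, and Bonferroni-adjusted p-value), and \code{bySd} (ratio
#'   |mean|/sd per cell).
#' @export
evaluatePredictor <- function(model, test) {
  stopifnot(is(test, "LabeledDataset"))
  pred <- predictParameters(model, test)
  truthM <- parameterTargets(test)
  stopifnot(ncol(pred) == ncol(truthM))
  m <- ncol(pred) / 5L
  err <- pred - truthM
  parNames <- c("thetaP", "thetaC", "thetaA", "log10alpha", "log10sigma2")
  ## mean error across tissues per observation, per parameter type
  meanErr <- sapply(seq_len(5L), function(k)
    rowMeans(err[, (seq_len(m) - 1L) * 5L + k, drop = FALSE]))
  colnames(meanErr) <- parNames
  cls <- retentionClass(test)
  long <- data.frame(class = rep(cls, times = 5L),
                     parameter = rep(parNames, each = length(cls)),
                     meanError = as.vector(meanErr))
  cells <- expand.grid(class = unique(cls), parameter = parNames,
                       stringsAsFactors = FALSE)
  stats <- lapply(seq_len(nrow(cells)), function(i) {
    e <- long$meanError[long$class == cells$class[i] &
                        long$parameter == cells$parameter[i]]
    tt <- t.test(e, mu = 0)
    data.frame(class = cells$class[i], parameter = cells$parameter[i],
               mean = mean(e), sd = sd(e), n = length(e),
               pAdj = min(1, tt$p.value * nrow(cells)))
  })
  summary <- do.call(rbind, stats)
  summary$absMeanOverSd <- abs(summary$mean) / summary$sd
  list(errors = long, summary = summary)
}

#' Evaluate externally produced class calls
#'
#' Scores any classifier's hard calls (e.g. read from a TSV produced by
#' another tool) against the simulated truth with the same bookkeeping as
#' [evaluateClassifier()]: overall accuracy and the row-normalized
#' confusion matrix. No probabilities are involved, so no ROC is computed.
#'
#' @param calls character vector of retention class labels.
#' @param truth true labels (or a [LabeledDataset-class]).
#' @return list with \code{accuracy} and \code{confusion}.
#' @export
evaluateCalls <- function(calls, truth) {
  if (is(truth, "LabeledDataset")) truth <- retentionClass(truth)
  stopifnot(length(calls) == length(truth))
  if (!all(calls %in% retentionClasses()))
    stop("unknown retention class label in calls")
  lv <- retentionClasses()
  counts <- table(truth = factor(truth, levels = lv),
                  call = factor(calls, levels = lv))
  list(accuracy = mean(as.character(calls) == as.character(truth)),
       confusion = sweep(unclass(counts), 1L, pmax(1L, rowSums(counts)),
                         "/"))
}

#' Mixed-mechanism robustness test
#'
#' Simulates duplicates whose retention mechanism is non-uniform across
#' tissues: k tissues evolve under mechanism A and the remaining m - k under
#' mechanism B, with all parameters drawn from the training ranges. The
#' trained classifier's call frequencies are tabulated; when a predictor is
#' supplied, per-parameter mean errors (against the per-tissue truth) are
#' summarized as well.
#'
#' @param model a classifier [CloudModel-class].
#' @param mechA,mechB two distinct retention class labels.
#' @param k number of tissues under \code{mechA} (1 to m-1).
#' @param nReps number of replicate test observations (1,000 in the standard
#'   design).
#' @param m number of tissues.
#' @param background a [BackgroundDistributions-class].
#' @param ranges parameter ranges.
#' @param tpcPool optional duplication-time pool.
#' @param predictor optional predictor [CloudModel-class].
#' @param seed integer seed.
#' @return list with \code{callFrequencies} (named, over the five classes),
#'   \code{modalCall}, and optionally \code{parameterErrors} (per-parameter
#'   mean and sd of the tissue-averaged errors).
#' @export
mixedMechanismTest <- function(model, mechA, mechB, k, nReps = 1000L,
                               m = 6L, background,
                               ranges = parameterRanges(), tpcPool = NULL,
                               predictor = NULL, seed) {
  stopifnot(mechA %in% retentionClasses(), mechB %in% retentionClasses())
  if (mechA == mechB) stop("mechA and mechB must differ")
  if (k < 1L || k > m - 1L) stop("k must lie in 1..(m-1)")
  perTissue <- c(rep(mechA, k), rep(mechB, m - k))
  sc <- drawScenarios(perTissue, n = nReps, m = m, ranges = ranges,
                      tpcPool = tpcPool, seed = childSeed(seed, "mixed"))
  tr <- sampleExpressionTriplets(sc, seed = childSeed(seed, "mixed.expr"))
  x <- assembleFeatures(tr, tpcTimes(sc), background)
  calls <- classifyDuplicates(model, x)$labels
  freq <- table(factor(calls, levels = retentionClasses())) / length(calls)
  out <- list(callFrequencies = freq,
              modalCall = names(freq)[which.max(freq)],
              k = k, mechA = mechA, mechB = mechB)
  if (!is.null(predictor)) {
    pred <- predictParameters(predictor, x)
    truthM <- parameterTargets(sc)
    err <- pred - truthM
    parNames <- c("thetaP", "thetaC", "thetaA", "log10alpha", "log10sigma2")
    meanErr <- sapply(seq_len(5L), function(kk)
      rowMeans(err[, (seq_len(m) - 1L) * 5L + kk, drop = FALSE]))
    colnames(meanErr) <- parNames
    out$parameterErrors <- data.frame(parameter = parNames,
                                      mean = colMeans(meanErr),
                                      sd = apply(meanErr, 2L, sd))
  }
  out
}
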