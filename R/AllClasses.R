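#' @import methods
#' @importFrom stats cor rnorm runif sd var predict t.test ks.test setNames
#' @importFrom utils read.table write.table head
#' @useDynLib cloudr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Retention class labels
#'
#' The five duplicate-gene retention mechanisms, in their fixed integer
#' encoding (1 through 5). All class arguments and outputs in the package use
#' these labels; classifier output columns follow this order.
#'
#' @return Character vector of length five:
#'   \code{"Conserved"}, \code{"NeofunctionalizedParent"},
#'   \code{"NeofunctionalizedChild"}, \code{"Subfunctionalized"},
#'   \code{"Specialized"}.
#' @examples retentionClasses()
#' @export
retentionClasses <- function() {
  c("Conserved", "NeofunctionalizedParent", "NeofunctionalizedChild",
    "Subfunctionalized", "Specialized")
}

#' DuplicateScenarioSet: per-tissue OU parameters for simulated duplicates
#'
#' Container for a batch of n simulated duplicate-gene scenarios over m
#' tissues. Each scenario carries a scaled duplication time tPC (root height
#' fixed at 1), per-tissue optimal expression states for parent, child and
#' ancestral gene, per-tissue selection strength alpha and phenotypic drift
#' rate sigma2, and a per-tissue retention class label. Uniform scenarios
#' repeat one label across tissues; mixed-mechanism scenarios do not.
#'
#' @slot tPC numeric(n), scaled duplication times in (0, 1).
#' @slot thetaP,thetaC,thetaA n x m matrices of optimal expression states
#'   (log10 expression units).
#' @slot alpha n x m matrix of selection strengths (> 0, per unit tree height).
#' @slot sigma2 n x m matrix of drift variance rates (> 0).
#' @slot classes n x m character matrix of retention class labels.
#' @seealso [drawScenarios()], [sampleExpressionTriplets()]
#' @export
setClass("DuplicateScenarioSet",
  representation(tPC = "numeric", thetaP = "matrix", thetaC = "matrix",
                 thetaA = "matrix", alpha = "matrix", sigma2 = "matrix",
                 classes = "matrix"))

setValidity("DuplicateScenarioSet", function(object) {
  n <- length(object@tPC)
  dims <- vapply(list(object@thetaP, object@thetaC, object@thetaA,
                      object@alpha, object@sigma2, object@classes),
                 function(x) all(dim(x) == dim(object@thetaP)), logical(1))
  if (!all(dims)) return("per-tissue parameter matrices differ in dimension")
  if (nrow(object@thetaP) != n) return("tPC length does not match matrices")
  if (any(object@tPC <= 0 | object@tPC >= 1)) return("tPC must lie in (0, 1)")
  if (any(object@alpha <= 0)) return("alpha must be positive")
  if (any(object@sigma2 <= 0)) return("sigma2 must be positive")
  if (!all(object@classes %in% retentionClasses()))
    return("unknown retention class label")
  TRUE
})

#' BackgroundDistributions: single-copy divergence baseline
#'
#' Summaries of the genome-wide single-copy gene set G used as the divergence
#' baseline for the rank and moment features: the multiset of per-gene
#' between-species Euclidean distances dist(G), the multiset of per-gene
#' Pearson correlations cor(G), and the cached maximum of dist(G).
#'
#' @slot dist numeric, one Euclidean distance per single-copy gene.
#' @slot cor numeric in [-1, 1], one Pearson correlation per gene.
#' @slot maxDist numeric(1), max of \code{dist}.
#' @seealso [backgroundSummaries()], [simulateSingleCopySet()]
#' @export
setClass("BackgroundDistributions",
  representation(dist = "numeric", cor = "numeric", maxDist = "numeric"))

setValidity("BackgroundDistributions", function(object) {
  if (length(object@dist) == 0L) return("empty background")
  if (length(object@dist) != length(object@cor))
    return("dist and cor lengths differ")
  if (any(!is.finite(object@dist)) || any(object@dist < 0))
    return("distances must be finite and nonnegative")
  if (any(object@cor < -1 - 1e-12 | object@cor > 1 + 1e-12))
    return("correlations must lie in [-1, 1]")
  if (!isTRUE(all.equal(object@maxDist, max(object@dist))))
    return("maxDist does not match max(dist)")
  TRUE
})

#' LabeledDataset: features plus simulation truth
#'
#' A feature matrix (one row per simulated duplicate, p = 4m+84 columns in the
#' fixed feature order) together with the full scenario truth used to simulate
#' each row.
#'
#' @slot features N x p numeric matrix.
#' @slot scenarios [DuplicateScenarioSet-class] of length N.
#' @seealso [generateTrainingSet()], [generateTestSet()]
#' @export
setClass("LabeledDataset",
  representation(features = "matrix", scenarios = "DuplicateScenarioSet"))

setValidity("LabeledDataset", function(object) {
  if (nrow(object@features) != length(object@scenarios@tPC))
    return("feature rows do not match scenario count")
  TRUE
})

#' CloudModel: a trained classifier or parameter predictor
#'
#' Weights and biases of the dense feed-forward network, together with the
#' training-set feature scaling statistics, the network configuration, and
#' the feature/output naming needed to score new feature matrices. Models
#' refuse to score feature matrices whose column names differ from the ones
#' they were trained on.
#'
#' @slot weights list of L+1 weight matrices (layer l to l+1).
#' @slot biases list of L+1 bias vectors (one per destination unit).
#' @slot center,scale numeric(p) feature standardization statistics (all-zero
#'   center and unit scale when standardization is disabled).
#' @slot config list, see [networkConfig()].
#' @slot featureNames character(p), column names the model expects.
#' @slot outputNames character(K): class labels (classifier) or parameter
#'   names (predictor).
#' @slot task "classify" or "predict".
#' @slot costHistory numeric, mean penalized training cost per epoch.
#' @seealso [trainNetwork()], [classifyDuplicates()], [predictParameters()]
#' @export
setClass("CloudModel",
  representation(weights = "list", biases = "list", center = "numeric",
                 scale = "numeric", config = "list",
                 featureNames = "character", outputNames = "character",
                 task = "character", costHistory = "numeric"))

setValidity("CloudModel", function(object) {
  if (!object@task %in% c("classify", "predict")) return("unknown task")
  if (length(object@weights) != length(object@biases))
    return("weights and biases differ in layer count")
  p <- length(object@center)
  if (length(object@scale) != p) return("center/scale length mismatch")
  if (nrow(object@weights[[1L]]) != p) return("first layer width != p")
  K <- ncol(object@weights[[length(object@weights)]])
  if (length(object@outputNames) != K) return("outputNames length != K")
  TRUE
})

#' CloudCV: cross-validation results over (L, lambda, gamma)
#'
#' @slot grid data.frame with columns L, lambda, gamma and cvLoss (mean
#'   held-out validation loss over the five folds).
#' @slot best list(L, lambda, gamma, cvLoss) for the grid argmin.
#' @slot task "classify" or "predict".
#' @seealso [crossValidate()]
#' @export
setClass("CloudCV",
  representation(grid = "data.frame", best = "list", task = "character"))

## ---- accessors -------------------------------------------------------------

#' @describeIn DuplicateScenarioSet-class number of scenarios
#' @param object,x a DuplicateScenarioSet
#' @export
setMethod("length", "DuplicateScenarioSet", function(x) length(x@tPC))

#' Number of tissues of a scenario set, dataset or background-compatible object
#' @param object object with per-tissue structure
#' @export
setGeneric("nTissues", function(object) standardGeneric("nTissues"))

#' @rdname nTissues
#' @export
setMethod("nTissues", "DuplicateScenarioSet",
          function(object) ncol(object@thetaP))

#' Scaled duplication times
#' @param object a DuplicateScenarioSet or LabeledDataset
#' @export
setGeneric("tpcTimes", function(object) standardGeneric("tpcTimes"))

#' @rdname tpcTimes
#' @export
setMethod("tpcTimes", "DuplicateScenarioSet", function(object) object@tPC)

#' @rdname tpcTimes
#' @export
setMethod("tpcTimes", "LabeledDataset",
          function(object) object@scenarios@tPC)

#' Retention class of each scenario
#'
#' For uniform scenarios returns one label per scenario; with
#' \code{perTissue = TRUE} (or for mixed-mechanism scenarios) returns the full
#' n x m label matrix.
#' @param object a DuplicateScenarioSet or LabeledDataset
#' @param perTissue logical, return the n x m matrix
#' @export
setGeneric("retentionClass",
           function(object, perTissue = FALSE) standardGeneric("retentionClass"))

#' @rdname retentionClass
#' @export
setMethod("retentionClass", "DuplicateScenarioSet",
  function(object, perTissue = FALSE) {
    if (perTissue) return(object@classes)
    uni <- apply(object@classes, 1L, function(z) {
      u <- unique(z)
      if (length(u) == 1L) u else NA_character_
    })
    if (anyNA(uni))
      stop("scenario set mixes mechanisms across tissues; ",
           "use retentionClass(x, perTissue = TRUE)")
    uni
  })

#' @rdname retentionClass
#' @export
setMethod("retentionClass", "LabeledDataset",
  function(object, perTissue = FALSE)
    retentionClass(object@scenarios, perTissue))

#' Per-tissue OU parameters of a scenario set
#'
#' @param object a DuplicateScenarioSet
#' @return named list of n x m matrices
#'   (thetaP, thetaC, thetaA, alpha, sigma2).
#' @export
setGeneric("scenarioParameters",
           function(object) standardGeneric("scenarioParameters"))

#' @rdname scenarioParameters
#' @export
setMethod("scenarioParameters", "DuplicateScenarioSet", function(object)
  list(thetaP = object@thetaP, thetaC = object@thetaC,
       thetaA = object@thetaA, alpha = object@alpha, sigma2 = object@sigma2))

#' Feature matrix of a labeled dataset
#' @param object a LabeledDataset
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "LabeledDataset", function(object) object@features)

#' Scenario truth of a labeled dataset
#' @param object a LabeledDataset
#' @export
setGeneric("scenarios", function(object) standardGeneric("scenarios"))

#' @rdname scenarios
#' @export
setMethod("scenarios", "LabeledDataset", function(object) object@scenarios)

#' Background accessors
#' @param object a BackgroundDistributions
#' @export
setGeneric("distBackground", function(object) standardGeneric("distBackground"))
#' @rdname distBackground
#' @export
setMethod("distBackground", "BackgroundDistributions",
          function(object) object@dist)
#' @rdname distBackground
#' @export
setGeneric("corBackground", function(object) standardGeneric("corBackground"))
#' @rdname distBackground
#' @export
setMethod("corBackground", "BackgroundDistributions",
          function(object) object@cor)

#' Task of a trained model ("classify" or "predict")
#' @param object a CloudModel
#' @export
setGeneric("modelTask", function(object) standardGeneric("modelTask"))
#' @rdname modelTask
#' @export
setMethod("modelTask", "CloudModel", function(object) object@task)

#' Network configuration of a trained model
#' @param object a CloudModel
#' @export
setGeneric("modelConfig", function(object) standardGeneric("modelConfig"))
#' @rdname modelConfig
#' @export
setMethod("modelConfig", "CloudModel", function(object) object@config)

#' Selected hyperparameters of a cross-validation run
#' @param object a CloudCV
#' @export
setGeneric("bestHyperparameters",
           function(object) standardGeneric("bestHyperparameters"))
#' @rdname bestHyperparameters
#' @export
setMethod("bestHyperparameters", "CloudCV", function(object) object@best)

#' @rdname bestHyperparameters
#' @param object a CloudCV
#' @export
setGeneric("cvGrid", function(object) standardGeneric("cvGrid"))
#' @rdname bestHyperparameters
#' @export
setMethod("cvGrid", "CloudCV", function(object) object@grid)

## ---- show methods ----------------------------------------------------------

setMethod("show", "DuplicateScenarioSet", function(object) {
  n <- length(object)
  tab <- table(factor(object@classes, levels = retentionClasses()))
  cat("DuplicateScenarioSet with", n, "scenarios over",
      nTissues(object), "tissues\n")
  cat("  tPC range: [", signif(min(object@tPC), 3), ", ",
      signif(max(object@tPC), 3), "]\n", sep = "")
  cat("  tissue-level class counts:\n")
  print(tab)
})

setMethod("show", "BackgroundDistributions", function(object) {
  cat("BackgroundDistributions over", length(object@dist),
      "single-copy genes\n")
  cat("  dist(G): median", signif(stats::median(object@dist), 4),
      " max", signif(object@maxDist, 4), "\n")
  cat("  cor(G): median", signif(stats::median(object@cor), 4), "\n")
})

setMethod("show", "LabeledDataset", function(object) {
  cat("LabeledDataset:", nrow(object@features), "observations x",
      ncol(object@features), "features\n")
  show(object@scenarios)
})

setMethod("show", "CloudModel", function(object) {
  widths <- vapply(object@weights, ncol, integer(1))
  cat("CloudModel (", object@task, ")\n", sep = "")
  cat("  architecture: ", length(object@center), " -> ",
      paste(widths, collapse = " -> "), "\n", sep = "")
  cat("  lambda =", object@config$lambda, " gamma =", object@config$gamma,
      " epochs =", object@config$epochs, "\n")
  if (length(object@costHistory))
    cat("  final training cost:",
        signif(object@costHistory[length(object@costHistory)], 5), "\n")
})

setMethod("show", "CloudCV", function(object) {
  cat("CloudCV (", object@task, "): ", nrow(object@grid),
      " grid points\n", sep = "")
  cat("  best: L =", object@best$L, " lambda =", object@best$lambda,
      " gamma =", object@best$gamma,
      " cvLoss =", signif(object@best$cvLoss, 5), "\n")
})
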