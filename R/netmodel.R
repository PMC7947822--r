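## The classifier / predictor surface around the compiled network core:
## configuration, Glorot initialization, feature standardization, training,
## cost evaluation, scoring and stratified five-fold cross-validation over
## (L, lambda, gamma).

#' Hidden-layer widths of the network
#'
#' The first hidden layer has 256 units and each subsequent hidden layer has
#' half the units of the previous one (256, 128, 64 for L = 3).
#' @param L number of hidden layers (0 to 3).
#' @return integer vector of length L (empty for L = 0).
#' @export
hiddenWidths <- function(L) {
  stopifnot(L %in% 0:3)
  if (L == 0L) integer(0) else as.integer(256 / 2^(seq_len(L) - 1L))
}

#' Network configuration
#'
#' Collects every tunable of the network and its training loop with the
#' standard defaults: Adam with learning rate 1e-3, beta1 = 0.9,
#' beta2 = 0.999, epsilon = 1e-8; minibatches of 5000 observations; 500
#' epochs. \code{L = 0} reduces the classifier to multinomial regression and
#' the predictor to linear regression on the features.
#'
#' @param task "classify" (softmax head, categorical cross-entropy) or
#'   "predict" (linear head, per-observation residual sum of squares).
#' @param L number of hidden layers, 0 to 3.
#' @param lambda elastic-net penalty strength (>= 0) applied to all weights
#'   (never to biases).
#' @param gamma elastic-net mixing in [0, 1]: 0 = pure L2, 1 = pure L1.
#' @param learningRate,beta1,beta2,epsilon Adam settings.
#' @param batchSize minibatch size.
#' @param epochs training epochs.
#' @param standardize z-score each feature by training-set mean/sd before
#'   input (stored in the model and re-applied at scoring). On by default:
#'   rank features span 1 to |G|+1 while moment features are O(1), and
#'   penalized training is scale-sensitive.
#' @param scalarBiasPerLayer use a single shared bias per layer instead of
#'   one bias per unit (literal-notation mode; off by default).
#' @return named list of class settings for [trainNetwork()].
#' @export
networkConfig <- function(task = c("classify", "predict"), L = 2L,
                          lambda = 0, gamma = 0, learningRate = 1e-3,
                          beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                          batchSize = 5000L, epochs = 500L,
                          standardize = TRUE, scalarBiasPerLayer = FALSE) {
  task <- match.arg(task)
  stopifnot(L %in% 0:3, lambda >= 0, gamma >= 0, gamma <= 1,
            learningRate > 0, batchSize >= 1L, epochs >= 1L)
  list(task = task, L = as.integer(L), lambda = lambda, gamma = gamma,
       learningRate = learningRate, beta1 = beta1, beta2 = beta2,
       epsilon = epsilon, batchSize = as.integer(batchSize),
       epochs = as.integer(epochs), standardize = isTRUE(standardize),
       scalarBiasPerLayer = isTRUE(scalarBiasPerLayer))
}

## Glorot-uniform initial weights; biases start at zero.
.initWeights <- function(p, K, L, seed, scalarBias) {
  widths <- c(p, hiddenWidths(L), K)
  set.seed(childSeed(seed, "init"))
  W <- vector("list", length(widths) - 1L)
  b <- vector("list", length(widths) - 1L)
  for (l in seq_along(W)) {
    fanIn <- widths[l]; fanOut <- widths[l + 1L]
    lim <- sqrt(6 / (fanIn + fanOut))
    W[[l]] <- matrix(runif(fanIn * fanOut, -lim, lim), fanIn, fanOut)
    b[[l]] <- numeric(fanOut)
  }
  list(W = W, b = b)
}

.oneHot <- function(labels) {
  f <- factor(labels, levels = retentionClasses())
  if (anyNA(f)) stop("unknown retention class label in training labels")
  Y <- matrix(0, length(f), nlevels(f))
  Y[cbind(seq_along(f), as.integer(f))] <- 1
  colnames(Y) <- levels(f)
  Y
}

.standardizeStats <- function(x, enable) {
  if (!enable)
    return(list(center = numeric(ncol(x)), scale = rep(1, ncol(x))))
  ctr <- colMeans(x)
  scl <- apply(x, 2L, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

.applyScaling <- function(x, center, scale)
  sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")

#' Train the classifier or parameter predictor
#'
#' Minimizes the elastic-net-penalized cost
#' \deqn{J = (1/N) \sum_i L(\hat y^{(i)}, y^{(i)}) +
#'   \lambda \sum_{\ell,j,k} [(1-\gamma) (w^{[\ell]}_{jk})^2 +
#'   \gamma |w^{[\ell]}_{jk}|]}
#' by minibatch Adam, where the loss is the categorical cross-entropy
#' (classification) or the residual sum of squares over the K outputs
#' (prediction). Weights are Glorot-uniform initialized; features are
#' z-scored by training statistics when \code{standardize} is on. Training
#' is deterministic given the seed.
#'
#' @param x N x p feature matrix (columns named as [featureNames()]), or a
#'   [LabeledDataset-class].
#' @param y class labels (character/factor) for the classifier, or an
#'   N x K numeric target matrix for the predictor; may be omitted when
#'   \code{x} is a LabeledDataset (labels / [parameterTargets()] are used).
#' @param config a [networkConfig()].
#' @param seed integer seed governing initialization and batch shuffling.
#' @return a [CloudModel-class].
#' @examples
#' \donttest{
#' ds <- generateTrainingSet(nPerClass = 200, seed = 1,
#'   background = fixtureBackground(500, seed = 1))
#' cfg <- networkConfig("classify", L = 0, epochs = 50, batchSize = 1000)
#' fit <- trainNetwork(ds, config = cfg, seed = 1)
#' }
#' @export
trainNetwork <- function(x, y = NULL, config = networkConfig(), seed) {
  if (is(x, "LabeledDataset")) {
    if (is.null(y))
      y <- if (config$task == "classify") retentionClass(x)
           else parameterTargets(x)
    x <- featureMatrix(x)
  }
  stopifnot(is.matrix(x))
  if (config$task == "classify") {
    Y <- .oneHot(y)
    outNames <- colnames(Y)
  } else {
    Y <- as.matrix(y)
    if (nrow(Y) != nrow(x)) stop("target rows do not match feature rows")
    outNames <- colnames(Y)
    if (is.null(outNames)) outNames <- paste0("y", seq_len(ncol(Y)))
  }
  sc <- .standardizeStats(x, config$standardize)
  xs <- .applyScaling(x, sc$center, sc$scale)
  init <- .initWeights(ncol(x), ncol(Y), config$L, seed,
                       config$scalarBiasPerLayer)
  fit <- cpp_nn_train(xs, Y, init$W, init$b,
                      if (config$task == "classify") 0L else 1L,
                      config$lambda, config$gamma, config$learningRate,
                      config$beta1, config$beta2, config$epsilon,
                      config$batchSize, config$epochs,
                      childSeed(seed, "batches"), config$scalarBiasPerLayer)
  fn <- colnames(x)
  if (is.null(fn)) fn <- paste0("x", seq_len(ncol(x)))
  new("CloudModel", weights = fit$weights, biases = fit$biases,
      center = unname(sc$center), scale = unname(sc$scale), config = config,
      featureNames = fn, outputNames = outNames, task = config$task,
      costHistory = fit$costHistory)
}

.checkFeatures <- function(model, x) {
  if (is(x, "LabeledDataset")) x <- featureMatrix(x)
  stopifnot(is.matrix(x))
  if (ncol(x) != length(model@featureNames))
    stop("feature matrix has ", ncol(x), " columns; model expects ",
         length(model@featureNames))
  if (!is.null(colnames(x)) &&
      !identical(colnames(x), model@featureNames))
    stop("feature column names do not match the model's feature version")
  x
}

#' Forward pass of a trained model
#'
#' Applies the stored feature scaling and the network. Classifier output
#' rows are softmax probabilities over the five retention classes; predictor
#' output rows are the K = 5m parameter estimates.
#'
#' @param model a [CloudModel-class].
#' @param x feature matrix or [LabeledDataset-class].
#' @return N x K numeric matrix.
#' @export
forwardPass <- function(model, x) {
  x <- .checkFeatures(model, x)
  xs <- .applyScaling(x, model@center, model@scale)
  out <- cpp_nn_forward(model@weights, model@biases, xs,
                        if (model@task == "classify") 0L else 1L)
  colnames(out) <- model@outputNames
  out
}

#' Penalized training cost of a model on a dataset
#'
#' Mean per-observation loss plus the elastic-net penalty over all weights
#' (biases unpenalized). With \code{lambda = 0} this is exactly the mean
#' loss.
#'
#' @param model a [CloudModel-class].
#' @param x feature matrix or [LabeledDataset-class].
#' @param y labels or targets (optional for a LabeledDataset).
#' @param lambda,gamma penalty settings; default to the model's own.
#' @return numeric(1).
#' @export
networkCost <- function(model, x, y = NULL, lambda = model@config$lambda,
                        gamma = model@config$gamma) {
  loss <- meanLoss(model, x, y)
  pen <- 0
  for (W in model@weights)
    pen <- pen + (1 - gamma) * sum(W^2) + gamma * sum(abs(W))
  loss + lambda * pen
}

#' Mean unpenalized loss of a model on a dataset
#'
#' Categorical cross-entropy (classifier) or the per-observation residual
#' sum of squares over the K outputs (predictor), averaged over
#' observations; this is the validation-loss statistic used in
#' cross-validation.
#'
#' @inheritParams networkCost
#' @export
meanLoss <- function(model, x, y = NULL) {
  if (is(x, "LabeledDataset") && is.null(y))
    y <- if (model@task == "classify") retentionClass(x)
         else parameterTargets(x)
  out <- forwardPass(model, x)
  if (model@task == "classify") {
    Y <- .oneHot(y)
    p <- pmax(out, 1e-12)
    mean(-rowSums(Y * log(p)))
  } else {
    mean(rowSums((out - as.matrix(y))^2))
  }
}

#' Classify duplicate genes
#'
#' @param model a classifier [CloudModel-class].
#' @param x feature matrix or [LabeledDataset-class].
#' @return list with \code{probabilities} (N x 5 matrix) and \code{labels}
#'   (character; argmax with ties broken toward the lowest class index).
#' @export
classifyDuplicates <- function(model, x) {
  if (modelTask(model) != "classify") stop("model task is not 'classify'")
  probs <- forwardPass(model, x)
  list(probabilities = probs,
       labels = colnames(probs)[max.col(probs, ties.method = "first")])
}

#' Predict per-tissue evolutionary parameters
#'
#' @param model a predictor [CloudModel-class].
#' @param x feature matrix or [LabeledDataset-class].
#' @return N x 5m matrix ordered (thetaP, thetaC, thetaA, log10 alpha,
#'   log10 sigma2) per tissue; alpha and sigma2 are on the log10 scale and
#'   may extrapolate beyond the training range (linear output head).
#' @export
predictParameters <- function(model, x) {
  if (modelTask(model) != "predict") stop("model task is not 'predict'")
  forwardPass(model, x)
}

## Stratified fold assignment: within each stratum, observations are
## permuted and folds filled round-robin, so every fold is class-balanced
## for a balanced input.
.foldAssignment <- function(strata, nFolds, seed) {
  set.seed(childSeed(seed, "folds"))
  fold <- integer(length(strata))
  for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  fold
}

#' Five-fold cross-validation over (L, lambda, gamma)
#'
#' Stratified k-fold cross-validation of the classifier or predictor. Each
#' fold trains on (k-1)/k of the observations and evaluates the unpenalized
#' validation loss (mean categorical cross-entropy, or mean per-observation
#' residual sum of squares) on the held-out fold; the grid point minimizing
#' the fold-averaged loss is selected. For the balanced 50,000-observation
#' training design this gives 40,000/10,000 splits with 8,000/2,000
#' observations per class. Fold membership is shared across grid points, so
#' duplicated grid points yield identical losses.
#'
#' @param x feature matrix or [LabeledDataset-class].
#' @param y labels (classifier) or target matrix (predictor); optional for a
#'   LabeledDataset.
#' @param grid data.frame with columns \code{L}, \code{lambda},
#'   \code{gamma}; defaults to the standard grid of L in 0..3, gamma in
#'   \{0, 0.1, ..., 1\} and 25 lambda values log-uniform on
#'   log10(lambda) in [-12, -3] (see [standardCVGrid()]).
#' @param config base [networkConfig()] supplying all non-grid settings.
#' @param nFolds number of folds (5).
#' @param seed integer seed (fold assignment and per-fold training).
#' @return a [CloudCV-class].
#' @export
crossValidate <- function(x, y = NULL, grid = standardCVGrid(),
                          config = networkConfig(), nFolds = 5L, seed) {
  if (is(x, "LabeledDataset")) {
    if (is.null(y))
      y <- if (config$task == "classify") retentionClass(x)
           else parameterTargets(x)
    strata <- retentionClass(x)
    x <- featureMatrix(x)
  } else {
    strata <- if (config$task == "classify") as.character(y)
              else rep("all", nrow(x))
  }
  if (nrow(grid) == 0L) stop("empty hyperparameter grid")
  stopifnot(all(c("L", "lambda", "gamma") %in% names(grid)))
  fold <- .foldAssignment(strata, nFolds, seed)
  yMat <- if (config$task == "predict") as.matrix(y)
  losses <- matrix(NA_real_, nrow(grid), nFolds)
  for (g in seq_len(nrow(grid))) {
    cfg <- config
    cfg$L <- as.integer(grid$L[g])
    cfg$lambda <- grid$lambda[g]
    cfg$gamma <- grid$gamma[g]
    for (f in seq_len(nFolds)) {
      tr <- fold != f
      ytr <- if (config$task == "classify") y[tr] else yMat[tr, , drop = FALSE]
      yva <- if (config$task == "classify") y[!tr]
             else yMat[!tr, , drop = FALSE]
      fit <- trainNetwork(x[tr, , drop = FALSE], ytr, cfg,
                          seed = childSeed(seed, sprintf("fold%02d", f)))
      losses[g, f] <- meanLoss(fit, x[!tr, , drop = FALSE], yva)
    }
  }
  cv <- grid
  cv$cvLoss <- rowMeans(losses)
  bestIdx <- which.min(cv$cvLoss)
  new("CloudCV", grid = cv,
      best = list(L = cv$L[bestIdx], lambda = cv$lambda[bestIdx],
                  gamma = cv$gamma[bestIdx], cvLoss = cv$cvLoss[bestIdx]),
      task = config$task)
}

#' The standard cross-validation grid
#'
#' L in \{0, 1, 2, 3\}, gamma in \{0, 0.1, ..., 1.0\} (11 points), and 25
#' lambda values spaced uniformly on log10(lambda) in [-12, -3].
#' The full grid has 4 x 11 x 25 = 1100 points; \code{L}, \code{gamma} and
#' \code{lambda} subsets can be supplied to restrict it.
#'
#' @param L,gamma,lambda optional restricted values.
#' @return data.frame with columns L, lambda, gamma.
#' @export
standardCVGrid <- function(L = 0:3, gamma = seq(0, 1, by = 0.1),
                           lambda = 10^seq(-12, -3, length.out = 25)) {
  expand.grid(L = L, lambda = lambda, gamma = gamma,
              KEEP.OUT.ATTRS = FALSE)
}

#' Serialize / restore a trained model as plain text
#'
#' Writes weights, biases, scaling statistics, configuration and the feature
#' name version to a plain-text file (dput format). [readCloudModel()]
#' restores the model; scoring a feature matrix whose header differs from
#' the stored feature version fails.
#'
#' @param model a [CloudModel-class].
#' @param path file path.
#' @export
writeCloudModel <- function(model, path) {
  stopifnot(is(model, "CloudModel"))
  obj <- list(weights = model@weights, biases = model@biases,
              center = model@center, scale = model@scale,
              config = model@config, featureNames = model@featureNames,
              outputNames = model@outputNames, task = model@task,
              costHistory = model@costHistory)
  dput(obj, file = path, control = c("keepNA", "keepInteger", "niceNames",
                                     "showAttributes", "digits17"))
  invisible(path)
}

#' @rdname writeCloudModel
#' @export
readCloudModel <- function(path) {
  obj <- dget(path)
  new("CloudModel", weights = obj$weights, biases = obj$biases,
      center = obj$center, scale = obj$scale, config = obj$config,
      featureNames = obj$featureNames, outputNames = obj$outputNames,
      task = obj$task, costHistory = obj$costHistory)
}
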