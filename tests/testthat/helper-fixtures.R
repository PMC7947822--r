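# Shared fixtures, all generated in code. Heavy objects (full-scale datasets
# and trained models) are built once per test run and cached, so every file
# that needs them reuses the same computation.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .cache, inherits = FALSE))
    assign(key, builder(), envir = .cache)
  get(key, envir = .cache, inherits = FALSE)
}

smallBackground <- function()
  cached("smallBackground", function() fixtureBackground(500, seed = 101))

fullBackground <- function()
  cached("fullBackground", function() fixtureBackground(10000, seed = 301))

fullTrainingSet <- function()
  cached("fullTrainingSet", function()
    generateTrainingSet(background = fullBackground(), seed = 302))

fullTestSet <- function()
  cached("fullTestSet", function()
    generateTestSet(background = fullBackground(), seed = 303))

classifierConfig <- function(...)
  networkConfig("classify", L = 2L, lambda = 1.778e-4, gamma = 1, ...)

predictorConfig <- function(...)
  networkConfig("predict", L = 2L, lambda = 7.499e-8, gamma = 0.8, ...)

# Full-scale headline classifier runs, one per replicate seed. Replicate 1
# reuses the shared full training/test sets; later replicates regenerate
# everything under fresh seeds.
headlineRun <- function(i) {
  cached(paste0("headlineRun", i), function() {
    if (i == 1L) {
      train <- fullTrainingSet(); test <- fullTestSet()
    } else {
      train <- generateTrainingSet(background = fullBackground(),
                                   seed = 310 + 2L * i)
      test <- generateTestSet(background = fullBackground(),
                              seed = 311 + 2L * i)
    }
    fit <- trainNetwork(train, config = classifierConfig(), seed = 320 + i)
    list(fit = fit, eval = evaluateClassifier(fit, test), test = test)
  })
}

fullPredictor <- function()
  cached("fullPredictor", function()
    trainNetwork(fullTrainingSet(), config = predictorConfig(), seed = 305))

# A quick (reduced-size) classifier for plumbing tests that only need a
# working model, not headline accuracy.
quickClassifier <- function()
  cached("quickClassifier", function() {
    train <- generateTrainingSet(nPerClass = 300,
                                 background = smallBackground(), seed = 111)
    cfg <- classifierConfig(epochs = 80L, batchSize = 750L)
    trainNetwork(train, config = cfg, seed = 112)
  })

randomTriplets <- function(n, m, seed) {
  set.seed(seed)
  matrix(rnorm(n * 3 * m), n, 3 * m)
}
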