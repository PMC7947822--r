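# Experiment harnesses: dataset plumbing, classifier/predictor evaluation,
# regime monotonicity, mixed-mechanism preconditions.

test_that("generated datasets carry balanced truth and matching features", {
  bg <- smallBackground()
  ds <- generateTrainingSet(nPerClass = 20, background = bg, seed = 51)
  expect_identical(nrow(featureMatrix(ds)), 100L)
  expect_identical(as.integer(table(retentionClass(ds))), rep(20L, 5L))
  # feature column 1 is the recorded tPC, row by row
  expect_equal(unname(featureMatrix(ds)[, 1]), tpcTimes(ds))
  ds1 <- generateTrainingSet(nPerClass = 1, background = bg, seed = 52)
  expect_identical(nrow(featureMatrix(ds1)), 5L)
  # the scale argument multiplies every per-class count
  ds2 <- generateTrainingSet(nPerClass = 20, background = bg, scale = 0.5,
                             seed = 53)
  expect_identical(nrow(featureMatrix(ds2)), 50L)
})

test_that("training and test streams are disjoint under a shared seed", {
  bg <- smallBackground()
  tr <- generateTrainingSet(nPerClass = 10, background = bg, seed = 54)
  te <- generateTestSet(nPerClass = 10, background = bg, seed = 54)
  expect_false(any(tpcTimes(tr) %in% tpcTimes(te)))
})

test_that("restricted regimes draw within the requested decades", {
  bg <- smallBackground()
  rng <- parameterRanges(log10alpha = c(0, 1), log10sigma2 = c(2, 3))
  te <- generateTestSet(nPerClass = 20, background = bg, ranges = rng,
                       seed = 55)
  p <- scenarioParameters(scenarios(te))
  expect_true(all(p$alpha >= 1 & p$alpha <= 10))
  expect_true(all(p$sigma2 >= 100 & p$sigma2 <= 1000))
})

test_that("classifier evaluation reports accuracy and a row-normalized confusion", {
  bg <- smallBackground()
  te <- generateTestSet(nPerClass = 40, background = bg, seed = 56)
  fit <- quickClassifier()
  ev <- evaluateClassifier(fit, te, roc = TRUE)
  expect_equal(unname(rowSums(ev$confusion)), rep(1, 5))
  expect_true(all(ev$confusion >= 0 & ev$confusion <= 1))
  # on a balanced set, accuracy is the mean of the confusion diagonal
  expect_equal(ev$accuracy, mean(diag(ev$confusion)))
  expect_length(ev$roc, 5L)
  expect_gt(ev$macroAUC, 0.5)
  expect_lte(ev$macroAUC, 1)
})

test_that("a constant-probability model scores at chance on a balanced set", {
  bg <- smallBackground()
  te <- generateTestSet(nPerClass = 30, background = bg, seed = 57)
  zero <- new("CloudModel",
              weights = list(matrix(0, 108, 5)), biases = list(numeric(5)),
              center = numeric(108), scale = rep(1, 108),
              config = networkConfig("classify", L = 0),
              featureNames = featureNames(6),
              outputNames = retentionClasses(), task = "classify",
              costHistory = numeric(0))
  ev <- evaluateClassifier(zero, te)
  expect_equal(ev$accuracy, 0.2)   # uniform probabilities, ties to class 1
  expect_equal(unname(ev$confusion[, "Conserved"]), rep(1, 5))
})

test_that("a truth-passthrough predictor evaluates to zero error", {
  bg <- smallBackground()
  te <- generateTestSet(nPerClass = 15, background = bg, seed = 58)
  truth <- parameterTargets(te)
  # oracle model: identity network over features that are the truth itself
  oracleDs <- new("LabeledDataset", features = truth,
                  scenarios = scenarios(te))
  oracle <- new("CloudModel",
                weights = list(diag(30)), biases = list(numeric(30)),
                center = numeric(30), scale = rep(1, 30),
                config = networkConfig("predict", L = 0,
                                       standardize = FALSE),
                featureNames = colnames(truth),
                outputNames = colnames(truth), task = "predict",
                costHistory = numeric(0))
  ev0 <- evaluatePredictor(oracle, oracleDs)
  expect_lt(max(abs(ev0$errors$meanError)), 1e-5)
  # the harness reports the full 5 classes x 5 parameters grid
  expect_identical(nrow(ev0$summary), 25L)
  cfg <- networkConfig("predict", L = 0, epochs = 30, batchSize = 75,
                       lambda = 0, gamma = 0)
  fit <- trainNetwork(featureMatrix(te), truth, cfg, seed = 59)
  ev <- evaluatePredictor(fit, te)
  expect_true(all(is.finite(ev$summary$mean)))
  expect_true(all(c("class", "parameter", "meanError") %in%
                  names(ev$errors)))
})

test_that("accuracy is monotone in regime difficulty", {
  bg <- fullBackground()
  fit <- headlineRun(1)$fit
  easy <- generateTestSet(nPerClass = 200, background = bg,
                          ranges = parameterRanges(log10alpha = c(2, 3),
                                                   log10sigma2 = c(-2, -1)),
                          seed = 60)
  hard <- generateTestSet(nPerClass = 200, background = bg,
                          ranges = parameterRanges(log10alpha = c(0, 1),
                                                   log10sigma2 = c(2, 3)),
                          seed = 61)
  accEasy <- evaluateClassifier(fit, easy)$accuracy
  accHard <- evaluateClassifier(fit, hard)$accuracy
  expect_gte(accEasy, accHard)
  # the strongly separated regime is essentially solved
  expect_gte(accEasy, 0.95)
})

test_that("external calls are scored with the same bookkeeping", {
  truth <- rep(retentionClasses(), each = 4)
  ev <- evaluateCalls(truth, truth)            # oracle calls
  expect_equal(ev$accuracy, 1)
  expect_equal(unname(diag(ev$confusion)), rep(1, 5))
  shuffled <- truth
  shuffled[1:2] <- "Specialized"
  ev2 <- evaluateCalls(shuffled, truth)
  expect_equal(ev2$accuracy, 18 / 20)
  expect_equal(unname(rowSums(ev2$confusion)), rep(1, 5))
  expect_error(evaluateCalls(rep("Lost", 20), truth), "unknown")
})

test_that("mixed-mechanism preconditions are enforced", {
  bg <- smallBackground()
  fit <- quickClassifier()
  expect_error(mixedMechanismTest(fit, "Conserved", "Conserved", k = 2,
                                  nReps = 5, background = bg, seed = 62),
               "must differ")
  expect_error(mixedMechanismTest(fit, "Conserved", "Specialized", k = 6,
                                  nReps = 5, background = bg, seed = 62),
               "k must lie")
  out <- mixedMechanismTest(fit, "Conserved", "Specialized", k = 2,
                            nReps = 20, background = bg, seed = 63)
  expect_equal(sum(out$callFrequencies), 1)
  expect_true(out$modalCall %in% retentionClasses())
})
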