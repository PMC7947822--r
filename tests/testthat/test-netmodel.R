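# Network surface: architecture, forward heads, cost, training, CV.

manualModel <- function(weights, biases, task, p, K,
                        outputNames = NULL, config = NULL) {
  if (is.null(outputNames))
    outputNames <- if (task == "classify") retentionClasses()
                   else paste0("y", seq_len(K))
  if (is.null(config))
    config <- networkConfig(task, L = 0, standardize = FALSE)
  new("CloudModel", weights = weights, biases = biases,
      center = numeric(p), scale = rep(1, p), config = config,
      featureNames = paste0("x", seq_len(p)), outputNames = outputNames,
      task = task, costHistory = numeric(0))
}

test_that("hidden layers halve in width from 256", {
  expect_identical(hiddenWidths(0), integer(0))
  expect_identical(hiddenWidths(3), c(256L, 128L, 64L))
  expect_error(hiddenWidths(4))
})

test_that("softmax head returns a probability simplex, linear head does not", {
  set.seed(31)
  W <- list(matrix(rnorm(3 * 5), 3, 5))
  b <- list(rnorm(5))
  mod <- manualModel(W, b, "classify", p = 3, K = 5)
  x <- matrix(rnorm(60), 20, 3)
  pr <- forwardPass(mod, x)
  expect_equal(unname(rowSums(pr)), rep(1, 20), tolerance = 1e-6)
  expect_true(all(pr > 0 & pr < 1))
  # all-zero weights: uniform class probabilities
  mod0 <- manualModel(list(matrix(0, 3, 5)), list(numeric(5)),
                      "classify", p = 3, K = 5)
  expect_equal(unname(forwardPass(mod0, x)), matrix(0.2, 20, 5),
               tolerance = 1e-6)
  # linear head passes the affine map through unchanged
  modL <- manualModel(W, b, "predict", p = 3, K = 5)
  expect_equal(unname(forwardPass(modL, x)),
               unname(sweep(x %*% W[[1]], 2, b[[1]], "+")),
               tolerance = 1e-5)
})

test_that("argmax calls are invariant to monotone logit rescaling", {
  set.seed(32)
  W <- matrix(rnorm(4 * 5), 4, 5)
  x <- matrix(rnorm(40), 10, 4)
  m1 <- manualModel(list(W), list(numeric(5)), "classify", 4, 5)
  m2 <- manualModel(list(3 * W), list(numeric(5)), "classify", 4, 5)
  expect_identical(classifyDuplicates(m1, x)$labels,
                   classifyDuplicates(m2, x)$labels)
})

test_that("the elastic-net penalty composes as printed", {
  # single weight w = 2, gamma = 0.5, lambda = 1: penalty 0.5*4 + 0.5*2 = 3
  mod <- manualModel(list(matrix(2, 1, 1)), list(0), "predict", 1, 1)
  x <- matrix(1, 4, 1); y <- matrix(2, 4, 1)   # predictions exactly 2
  expect_equal(meanLoss(mod, x, y), 0)
  expect_equal(networkCost(mod, x, y, lambda = 1, gamma = 0.5), 3)
  expect_equal(networkCost(mod, x, y, lambda = 0, gamma = 0.5), 0)
  # lambda = 0: cost equals the mean loss exactly
  y2 <- matrix(c(2, 2, 3, 3), 4, 1)
  expect_equal(networkCost(mod, x, y2, lambda = 0, gamma = 1),
               meanLoss(mod, x, y2))
  # perfect one-hot prediction has zero cross-entropy
  modC <- manualModel(list(matrix(c(100, 0, 0, 0, 0), 1, 5)), list(numeric(5)),
                      "classify", 1, 5)
  expect_equal(meanLoss(modC, matrix(1, 3, 1), rep("Conserved", 3)), 0,
               tolerance = 1e-6)
})

toyTwoClass <- function(n = 400, seed = 33) {
  set.seed(seed)
  half <- n / 2
  x <- rbind(cbind(rnorm(half, -2), rnorm(half, -2)),
             cbind(rnorm(half, 2), rnorm(half, 2)))
  colnames(x) <- c("x1", "x2")
  list(x = x, y = rep(c("Conserved", "Specialized"), each = half))
}

test_that("L = 0 training solves a separable toy problem like multinomial regression", {
  toy <- toyTwoClass()
  cfg <- networkConfig("classify", L = 0, lambda = 0, gamma = 0,
                       epochs = 500, batchSize = 100)
  fit <- trainNetwork(toy$x, toy$y, cfg, seed = 34)
  calls <- classifyDuplicates(fit, toy$x)$labels
  expect_gte(mean(calls == toy$y), 0.99)
  # independent reference fit: multinomial regression on the same features
  ref <- nnet::multinom(y ~ x1 + x2,
                        data = data.frame(toy$x, y = factor(toy$y)),
                        trace = FALSE)
  refCalls <- as.character(predict(ref, data.frame(toy$x)))
  expect_gte(mean(calls == refCalls), 0.98)
})

test_that("training cost decreases on a convex L = 0 problem", {
  toy <- toyTwoClass(seed = 35)
  cfg <- networkConfig("classify", L = 0, lambda = 0, gamma = 0,
                       epochs = 100, batchSize = 100)
  fit <- trainNetwork(toy$x, toy$y, cfg, seed = 36)
  h <- fit@costHistory
  expect_lt(mean(tail(h, 10)), mean(head(h, 10)))
  expect_true(all(is.finite(h)))
  expect_length(h, 100)
})

test_that("training is reproducible given the seed", {
  toy <- toyTwoClass(seed = 37)
  cfg <- networkConfig("classify", L = 1, lambda = 1e-5, gamma = 0.5,
                       epochs = 30, batchSize = 100)
  f1 <- trainNetwork(toy$x, toy$y, cfg, seed = 38)
  f2 <- trainNetwork(toy$x, toy$y, cfg, seed = 38)
  f3 <- trainNetwork(toy$x, toy$y, cfg, seed = 39)
  expect_identical(f1@weights, f2@weights)
  expect_identical(f1@biases, f2@biases)
  expect_false(identical(f1@weights, f3@weights))
})

test_that("an overwhelming penalty drives all weights to zero", {
  toy <- toyTwoClass(seed = 40)
  cfg <- networkConfig("classify", L = 0, lambda = 10, gamma = 0.5,
                       epochs = 500, batchSize = 50)
  fit <- trainNetwork(toy$x, toy$y, cfg, seed = 41)
  expect_lt(max(abs(fit@weights[[1]])), 0.01)
  pr <- forwardPass(fit, toy$x)
  # bias-only model: every observation gets the same class probabilities,
  # matching the (balanced two-class) priors on the used classes
  expect_lt(max(apply(pr, 2, sd)), 0.01)
  expect_equal(mean(pr[, "Conserved"]), mean(pr[, "Specialized"]),
               tolerance = 0.1)
})

test_that("models refuse mismatched feature versions", {
  toy <- toyTwoClass(seed = 42)
  cfg <- networkConfig("classify", L = 0, epochs = 5, batchSize = 400)
  fit <- trainNetwork(toy$x, toy$y, cfg, seed = 43)
  bad <- toy$x
  colnames(bad) <- c("x2", "x1")
  expect_error(forwardPass(fit, bad), "feature")
  expect_error(forwardPass(fit, toy$x[, 1, drop = FALSE]), "columns")
  expect_error(predictParameters(fit, toy$x), "task")
})

test_that("models round-trip through text serialization", {
  toy <- toyTwoClass(seed = 44)
  cfg <- networkConfig("classify", L = 1, epochs = 10, batchSize = 400)
  fit <- trainNetwork(toy$x, toy$y, cfg, seed = 45)
  path <- withr::local_tempfile(fileext = ".txt")
  writeCloudModel(fit, path)
  fit2 <- readCloudModel(path)
  expect_equal(forwardPass(fit2, toy$x), forwardPass(fit, toy$x))
})

test_that("cross-validation selects the argmin and repeats duplicated points", {
  toy <- toyTwoClass(n = 300, seed = 46)
  grid <- data.frame(L = c(0, 0, 0), lambda = c(1e-6, 5, 1e-6),
                     gamma = c(0, 0.5, 0))
  cfg <- networkConfig("classify", L = 0, epochs = 40, batchSize = 100)
  cv <- crossValidate(toy$x, toy$y, grid, cfg, nFolds = 5, seed = 47)
  g <- cvGrid(cv)
  expect_identical(g$cvLoss[1], g$cvLoss[3])   # duplicated grid point
  best <- bestHyperparameters(cv)
  expect_equal(best$cvLoss, min(g$cvLoss))
  expect_lt(g$cvLoss[1], g$cvLoss[2])          # huge penalty loses
  expect_error(crossValidate(toy$x, toy$y, grid[0, ], cfg, seed = 1),
               "empty")
})

test_that("stratified folds are class-balanced", {
  strata <- rep(retentionClasses(), each = 100)
  fold <- cloudr:::.foldAssignment(strata, 5L, seed = 48)
  expect_identical(as.integer(table(fold)), rep(100L, 5L))
  tab <- table(strata, fold)
  expect_true(all(tab == 20L))
})

test_that("the standard CV grid has the documented shape", {
  g <- standardCVGrid()
  expect_identical(nrow(g), 4L * 25L * 11L)
  expect_identical(sort(unique(g$gamma)), seq(0, 1, by = 0.1))
  expect_equal(range(log10(g$lambda)), c(-12, -3))
  expect_length(unique(g$lambda), 25L)
})
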