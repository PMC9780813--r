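test_that("parameter counting follows the closed form", {
  expect_identical(countParameters(cnnModelSpec()), 519249L)
  expect_equal(round(countParameters(cnnModelSpec()) / 1e6, 2), 0.52)
  expect_identical(countParameters(cnnModelSpec(padding = "same")), 525393L)
  # per-layer arithmetic: first block 3*3*1*64 + 64 = 640; an 8x8 input
  # gives a 3x3 map after one valid conv + pool, so flatten is 576
  expect_identical(countParameters(cnnModelSpec(filters = 64, dropout = 0,
                                                inputSize = 8)),
                   640L + (576L * 8L + 8L) + 9L)
  # conv blocks removed: dense path on the flattened 64x64 input
  expect_identical(countParameters(cnnModelSpec(filters = integer(0),
                                                dropout = numeric(0))),
                   4096L * 8L + 8L + 9L)
  expect_error(cnnModelSpec(filters = c(8, 8), dropout = 0), "length")
  expect_error(countParameters(cnnModelSpec(inputSize = 16)), "too small")
})

test_that("realized models match the closed-form count across specs", {
  grid <- list(
    cnnModelSpec(),
    cnnModelSpec(padding = "same"),
    cnnModelSpec(filters = c(8, 16, 8, 4)),
    cnnModelSpec(filters = c(4, 8), dropout = c(0, 0), inputSize = 32),
    cnnModelSpec(filters = c(4, 8), dropout = c(0, 0), inputSize = 32,
                 padding = "same"),
    cnnModelSpec(filters = c(12, 6, 4), dropout = c(0.25, 0, 0.25),
                 inputSize = 40))
  for (spec in grid) {
    m <- buildModel(spec, seed = 3)
    expect_identical(m$nParams, countParameters(spec))
    expect_identical(countParameters(m), countParameters(spec))
  }
})

test_that("model building is seeded and spec-shaped", {
  a <- buildModel(seed = 4)
  b <- buildModel(seed = 4)
  expect_identical(a$conv[[2]]$W, b$conv[[2]]$W)
  expect_identical(dim(a$conv[[1]]$W), c(3L, 3L, 1L, 64L))
  expect_identical(dim(a$conv[[4]]$W), c(3L, 3L, 256L, 64L))
  expect_identical(dim(a$dense1$W), c(8L, 256L))
})

test_that("evaluation metrics agree with the confusion counts", {
  perfect <- evaluateModel(c(0.9, 0.1, 0.8, 0.2), c(1, 0, 1, 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$precision, 1)

  probs <- c(rep(0.9, 99), 0.1, rep(0.05, 100))
  labels <- c(rep(1, 100), rep(0, 100))
  m <- evaluateModel(probs, labels)
  expect_equal(m$tp, 99); expect_equal(m$fn, 1)
  expect_equal(m$tn, 100); expect_equal(m$fp, 0)
  expect_equal(m$sensitivity, 0.99)
  expect_equal(m$specificity, 1)
  expect_equal(m$precision, 1)
  expect_equal(m$accuracy, (m$tp + m$tn) / 200)

  allNeg <- evaluateModel(rep(0.2, 4), c(1, 1, 0, 0))
  expect_equal(allNeg$sensitivity, 0)
  expect_true(is.na(allNeg$precision))
  expect_error(evaluateModel(0.5, c(0, 1)), "length")
  expect_error(evaluateModel(c(0.5, 0.6), c(0, 2)), "binary")
})

test_that("training is reproducible and validates its inputs", {
  set.seed(40)
  imgs <- lapply(1:20, function(i) matrix(sample(0:255, 4096, TRUE), 64, 64))
  s <- LabeledImageSet(imgs, id = sprintf("i%02d", 1:20),
                       class = rep(c("NORM", "ASMI"), 10))
  sp <- splitImageSet(s, splitSpec(0.25, seed = 1))
  cfg <- trainConfig(lr = 0.001, batchSize = 8, epochs = 2,
                     stepsPerEpoch = NULL, seed = 5)
  f1 <- trainModel(buildModel(seed = 5), sp$train, sp$validation, cfg)
  f2 <- trainModel(buildModel(seed = 5), sp$train, sp$validation, cfg)
  expect_identical(f1$metrics, f2$metrics)
  expect_identical(f1$model$conv[[1]]$W, f2$model$conv[[1]]$W)
  expect_equal(nrow(f1$history), 2L)
  expect_true(all(c("epoch", "loss", "val_accuracy") %in%
                    names(f1$history)))
  small <- LabeledImageSet(list(matrix(0L, 32, 32)), "a", "NORM")
  expect_error(trainModel(buildModel(seed = 1), small, small, cfg),
               "does not match")
})

test_that("the network learns a separable synthetic cohort", {
  fit <- smallFit()
  expect_gte(fit$metrics$accuracy, 0.9)
  # metrics are consistent with their confusion counts
  m <- fit$metrics
  expect_equal(m$accuracy,
               (m$tp + m$tn) / (m$tp + m$tn + m$fp + m$fn))
})
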