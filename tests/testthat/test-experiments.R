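test_that("default learning-rate list is the five standard values", {
  expect_identical(eval(formals(sweepLearningRates)$rates),
                   c(0.1, 0.01, 0.001, 1e-4, 1e-5))
  expect_error(sweepLearningRates(smallSets(), rates = numeric(0)),
               "non-empty")
  expect_error(sweepLearningRates(smallSets(), rates = c(0.1, -1)), "> 0")
})

test_that("a coarse rate underperforms the optimum on separable data", {
  sets <- smallSets()
  sw <- sweepLearningRates(sets, rates = c(0.1, 0.001),
                           trainCfg = smallTrainConfig())
  expect_equal(nrow(sw), 2L)
  acc <- setNames(sw$val_accuracy, sw$learning_rate)
  expect_lt(acc[["0.1"]], acc[["0.001"]])
  expect_gte(acc[["0.001"]], 0.9)
})

test_that("a single-rate sweep reduces to one training run", {
  sets <- smallSets()
  sw <- sweepLearningRates(sets, rates = 0.001,
                           trainCfg = smallTrainConfig())
  fit <- smallFit()
  expect_equal(sw$val_accuracy, fit$metrics$accuracy)
  expect_equal(sw$final_loss, fit$metrics$loss)
})

test_that("the native-rate sweep row reproduces the direct pipeline", {
  co <- smallCohort()
  sw <- sweepSamplingRates(co$records, co$labels, rates = c(100, 25),
                           trainCfg = smallTrainConfig(),
                           split = splitSpec(1/3, seed = 21))
  direct <- runPipelineExperiment(co$records, co$labels,
                                  trainCfg = smallTrainConfig(),
                                  split = splitSpec(1/3, seed = 21))
  native <- sw[sw$sampling_rate == 100, ]
  expect_equal(native$val_accuracy, direct$fit$metrics$accuracy)
  expect_equal(native$final_loss, direct$fit$metrics$loss)
  # sub-2 Hz class contrast survives 25 Hz resampling (Nyquist 12.5 > 2)
  expect_gt(sw$val_accuracy[sw$sampling_rate == 25], 0.65)
})

test_that("resampling to 25 Hz yields 250-sample signals", {
  co <- smallCohort()
  sel <- selectLead(co$records[[1]], "v1")
  expect_length(resampleSignal(sel$samples, sel$fs, 25), 250L)
})

test_that("representation comparison pairs arms and measures sizes", {
  co <- smallCohort()
  dir <- withr::local_tempdir()
  cmp <- compareRepresentations(co$records, co$labels,
                                trainCfg = smallTrainConfig(epochs = 2),
                                split = splitSpec(1/3, seed = 21),
                                dir = dir)
  for (arm in c("spectrogram", "raw")) {
    m <- cmp[[arm]]$metrics
    expect_true(all(c("accuracy", "precision", "sensitivity",
                      "specificity", "loss") %in% names(m)))
  }
  # both arms saw the identical record set
  ms <- read.csv(file.path(dir, "spectrogram", "manifest.csv"))
  mr <- read.csv(file.path(dir, "raw", "manifest.csv"))
  expect_setequal(ms$id, mr$id)
  sz <- cmp$sizes
  expect_equal(nrow(sz), 2L)
  expect_equal(sz$images, rep(length(co$records), 2L))
  # byte totals agree with an independent directory walk
  for (i in 1:2) {
    files <- list.files(sz$path[i], recursive = TRUE, full.names = TRUE)
    expect_equal(sz$bytes[i], sum(file.size(files)))
  }
  expect_true(all(sz$bytes_per_image > 0))
})

test_that("size reports are byte-exact and handle empty directories", {
  d <- withr::local_tempdir()
  empty <- file.path(d, "empty"); dir.create(empty)
  writeBin(raw(100), file.path(d, "a.bin"))
  writeBin(raw(200), file.path(d, "b.bin"))
  rep <- datasetSizeReport(c(two = d, none = empty))
  expect_equal(rep$bytes[rep$dataset == "two"], 300)
  expect_equal(rep$bytes[rep$dataset == "none"], 0)
  expect_equal(rep$images, c(0L, 0L))
  # independent recount
  expect_equal(rep$bytes[1],
               sum(file.size(list.files(d, recursive = TRUE,
                                        full.names = TRUE))))
  expect_error(datasetSizeReport(file.path(d, "missing")), "exist")
})

test_that("run manifests capture config and seeds as JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  saveRunManifest(path, pipelineConfig(), trainConfig(seed = 42),
                  extra = list(cohort_seed = 11))
  m <- jsonlite::read_json(path)
  expect_equal(m$training$seed, 42L)
  expect_equal(m$pipeline$cutoff, 2)
  expect_equal(m$cohort_seed, 11L)
})
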