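# Desk-scale experiment grid: learning-rate sweep, sampling-rate sweep,
# spectrogram-versus-raw comparison, and on-disk dataset size accounting.
# Every run is reproducible from (config, seed); a JSON run manifest can
# record both.

# shared scaffold: images -> balance -> stratified split -> train
.trainOnSets <- function(sets, trainCfg, modelSeed = trainCfg$seed) {
  model <- buildModel(cnnModelSpec(), seed = modelSeed)
  trainModel(model, sets$train, sets$validation, trainCfg)
}

#' Run the full pipeline experiment on a cohort
#'
#' Converts records to images, balances classes, splits train/validation,
#' builds and trains the CNN, and reports validation metrics.
#'
#' @param records List of [EcgRecord-class] objects.
#' @param labels Label `data.frame` (`record_id`, `class`).
#' @param config A [pipelineConfig()].
#' @param trainCfg A [trainConfig()].
#' @param split A [splitSpec()].
#' @param verbose Print per-stage timings.
#' @return List with `fit` (see [trainModel()]), `sets` and `images`.
#' @export
runPipelineExperiment <- function(records, labels,
                                  config = pipelineConfig(),
                                  trainCfg = trainConfig(),
                                  split = splitSpec(), verbose = FALSE) {
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- force(expr)
    if (verbose)
      message(sprintf("[%s] %.1f s", name,
                      as.numeric(Sys.time() - t0, units = "secs")))
    out
  }
  images <- stage("images", buildImageDataset(records, labels, config))
  balanced <- stage("balance", balanceClasses(images, seed = split$seed))
  sets <- stage("split", splitImageSet(balanced, split))
  fit <- stage("train", .trainOnSets(sets, trainCfg))
  list(fit = fit, sets = sets, images = images)
}

#' Learning-rate sweep
#'
#' Trains the identical architecture on identical data and seeds, varying
#' only the learning rate. Default rate list: 0.1, 0.01, 0.001, 1e-4,
#' 1e-5.
#'
#' @param sets List with `train` and `validation`
#'   [LabeledImageSet-class] objects (e.g. from [splitImageSet()]).
#' @param rates Positive learning rates to evaluate.
#' @param trainCfg A [trainConfig()]; its `lr` is replaced per row.
#' @return `data.frame` of class `"SweepResult"`: columns
#'   `learning_rate`, `val_accuracy`, `final_loss`, `seed`.
#' @export
sweepLearningRates <- function(sets,
                               rates = c(0.1, 0.01, 0.001, 1e-4, 1e-5),
                               trainCfg = trainConfig()) {
  if (!length(rates)) stop("rate list must be non-empty")
  if (any(rates <= 0)) stop("learning rates must be > 0")
  rows <- lapply(rates, function(r) {
    cfg <- trainCfg
    cfg$lr <- r
    fit <- .trainOnSets(sets, cfg)
    data.frame(learning_rate = r,
               val_accuracy = fit$metrics$accuracy,
               final_loss = fit$metrics$loss,
               seed = trainCfg$seed)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("SweepResult", "data.frame")
  attr(out, "kind") <- "learning_rate"
  out
}

#' Sampling-rate sweep
#'
#' For each rate, resamples every record's analysis lead, runs the full
#' pipeline (denoise, frequency deletion, STFT at the resampled rate,
#' CNN training) with all seeds fixed, and records validation accuracy.
#' A rate equal to the native sampling rate reproduces the unresampled
#' pipeline exactly.
#'
#' @param records List of [EcgRecord-class] objects.
#' @param labels Label `data.frame`.
#' @param rates Positive sampling rates in Hz (default
#'   25, 50, 100, 200, 400, 600, 800, 1000).
#' @param config A [pipelineConfig()].
#' @param trainCfg A [trainConfig()].
#' @param split A [splitSpec()].
#' @return `data.frame` of class `"SweepResult"`: columns `sampling_rate`,
#'   `val_accuracy`, `final_loss`, `seed`.
#' @export
sweepSamplingRates <- function(records, labels,
                               rates = c(25, 50, 100, 200, 400, 600, 800,
                                         1000),
                               config = pipelineConfig(),
                               trainCfg = trainConfig(),
                               split = splitSpec()) {
  if (any(rates <= 0)) stop("sampling rates must be > 0")
  rows <- lapply(rates, function(fsOut) {
    resampled <- lapply(records, function(rec) {
      sel <- selectLead(rec, config$lead)
      if (fsOut == sel$fs) return(rec)
      y <- resampleSignal(sel$samples, sel$fs, fsOut)
      EcgRecord(id = rec@id, signals = y, fs = fsOut, leads = config$lead,
                codes = rec@codes)
    })
    res <- runPipelineExperiment(resampled, labels, config, trainCfg,
                                 split)
    data.frame(sampling_rate = fsOut,
               val_accuracy = res$fit$metrics$accuracy,
               final_loss = res$fit$metrics$loss,
               seed = trainCfg$seed)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("SweepResult", "data.frame")
  attr(out, "kind") <- "sampling_rate"
  out
}

#' Compare spectrogram and raw-signal representations
#'
#' Runs both arms on the same records with identical seeds, architecture
#' and hyperparameters; also writes both image sets to disk and measures
#' their on-disk size.
#'
#' @param records List of [EcgRecord-class] objects.
#' @param labels Label `data.frame`.
#' @param config A [pipelineConfig()]; the `representation` field is set
#'   per arm.
#' @param trainCfg A [trainConfig()].
#' @param split A [splitSpec()].
#' @param dir Directory for the two PNG datasets (default a tempdir).
#' @return List with `spectrogram` and `raw` (each: `metrics`, `history`),
#'   and `sizes` (see [datasetSizeReport()]).
#' @export
compareRepresentations <- function(records, labels,
                                   config = pipelineConfig(),
                                   trainCfg = trainConfig(),
                                   split = splitSpec(),
                                   dir = tempfile("repcmp")) {
  arms <- list()
  paths <- character(0)
  for (rep in c("spectrogram", "raw")) {
    cfg <- config
    cfg$representation <- rep
    res <- runPipelineExperiment(records, labels, cfg, trainCfg, split)
    out <- file.path(dir, rep)
    writeImageDirectory(res$images, out)
    paths[rep] <- out
    arms[[rep]] <- list(metrics = res$fit$metrics,
                        history = res$fit$history)
  }
  arms$sizes <- datasetSizeReport(paths)
  arms
}

#' On-disk dataset size report
#'
#' Byte-exact sums of file sizes under each path, with image counts
#' (`.png` files) and bytes per image.
#'
#' @param paths Named character vector of directories.
#' @return `data.frame` with `path`, `bytes`, `images`,
#'   `bytes_per_image`.
#' @export
datasetSizeReport <- function(paths) {
  rows <- lapply(seq_along(paths), function(i) {
    p <- paths[i]
    if (!dir.exists(p) && !file.exists(p)) stop("path does not exist: ", p)
    files <- list.files(p, recursive = TRUE, full.names = TRUE)
    sizes <- file.size(files)
    nimg <- sum(grepl("\\.png$", files, ignore.case = TRUE))
    data.frame(path = unname(p),
               dataset = if (!is.null(names(paths)) &&
                             nzchar(names(paths)[i])) names(paths)[i]
                         else basename(p),
               bytes = if (length(sizes)) sum(sizes) else 0,
               images = nimg,
               bytes_per_image = if (nimg) sum(sizes[grepl(
                 "\\.png$", files, ignore.case = TRUE)]) / nimg else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Save a JSON run manifest
#'
#' Records the pipeline and training configuration, the seeds, and the R
#' version, so any experiment can be re-run from the manifest alone.
#'
#' @param path Output JSON path.
#' @param config A [pipelineConfig()].
#' @param trainCfg A [trainConfig()].
#' @param extra Optional named list of additional fields.
#' @return `path`, invisibly.
#' @export
saveRunManifest <- function(path, config = pipelineConfig(),
                            trainCfg = trainConfig(), extra = list()) {
  manifest <- c(list(
    pipeline = unclass(config),
    training = unclass(trainCfg),
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("ecgspectro"))),
    extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}
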