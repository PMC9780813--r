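# Record-to-image pipeline: lead selection, wavelet denoising, 2 Hz
# frequency-deletion reduction, STFT spectrogram rendering (or a raw-signal
# line plot for the comparison dataset).

#' Pipeline configuration
#'
#' @param lead Analysis lead (default `"v1"`).
#' @param denoise A [denoiseConfig()].
#' @param cutoff Frequency-deletion cutoff in Hz (default 2).
#' @param filterMode Deletion mode (see [filterFrequencies()]).
#' @param normalize Amplitude normalization flag for the reduced signal.
#' @param stft An [stftParams()] (its `fs` is overridden by each record's
#'   sampling rate).
#' @param imageSize Output image side length (default 64).
#' @param representation `"spectrogram"` (denoise, filter, STFT) or
#'   `"raw"` (denoise only, line-plot raster).
#' @param scale Spectrogram intensity scale (see [renderSpectrogram()]).
#' @return List of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(lead = "v1", denoise = denoiseConfig(),
                           cutoff = 2, filterMode = "symmetric",
                           normalize = FALSE, stft = stftParams(),
                           imageSize = 64,
                           representation = c("spectrogram", "raw"),
                           scale = "dB") {
  representation <- match.arg(representation)
  structure(list(lead = lead, denoise = denoise, cutoff = cutoff,
                 filterMode = filterMode, normalize = normalize,
                 stft = stft, imageSize = imageSize,
                 representation = representation, scale = scale),
            class = "PipelineConfig")
}

#' Process one record into a grayscale image
#'
#' Spectrogram representation: select the lead, denoise, delete frequency
#' bins above the cutoff, take the STFT of the reduced series and render
#' it. Raw representation: select the lead, denoise, rasterize the
#' denoised waveform as a line plot.
#'
#' @param record An [EcgRecord-class].
#' @param config A [pipelineConfig()].
#' @return Integer image matrix (`imageSize` square, 0..255).
#' @export
recordToImage <- function(record, config = pipelineConfig()) {
  sel <- selectLead(record, config$lead)
  den <- denoiseSignal(sel$samples, config$denoise)
  if (config$representation == "raw")
    return(renderRawSignal(den$signal, config$imageSize))
  red <- filterFrequencies(den$signal, sel$fs, config$cutoff,
                           config$filterMode, config$normalize)
  sp <- config$stft
  sp$fs <- sel$fs
  sg <- stftMatrix(red$samples, sp)
  renderSpectrogram(sg, config$imageSize, config$scale)
}

#' Build a labeled image dataset from records
#'
#' @param records List of [EcgRecord-class] objects.
#' @param labels `data.frame` with `record_id` and `class` (e.g. from
#'   [generateCohort()] or [parseLabels()]).
#' @param config A [pipelineConfig()].
#' @return A [LabeledImageSet-class] with provenance `"original"`.
#' @export
buildImageDataset <- function(records, labels, config = pipelineConfig()) {
  ids <- vapply(records, recordId, "")
  cls <- labels$class[match(ids, labels$record_id)]
  if (anyNA(cls))
    stop("no label for record(s): ",
         paste(ids[is.na(cls)], collapse = ", "))
  images <- lapply(records, recordToImage, config = config)
  LabeledImageSet(images, id = ids, class = cls)
}

#' Write an image set to a class-per-directory PNG layout
#'
#' Layout `<root>/<class>/<id>_<provenance>.png` plus a `manifest.csv`
#' (id, class, provenance, file) at the root.
#'
#' @param set A [LabeledImageSet-class].
#' @param root Output directory.
#' @return The manifest path, invisibly.
#' @export
writeImageDirectory <- function(set, root) {
  meta <- set@meta
  counter <- new.env(parent = emptyenv())
  files <- character(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    dir <- file.path(root, meta$class[i])
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    base <- paste0(meta$id[i], "_", meta$provenance[i])
    k <- get0(base, envir = counter, ifnotfound = 0L) + 1L
    assign(base, k, envir = counter)
    name <- if (k == 1L) base else paste0(base, "_", k)
    files[i] <- file.path(dir, paste0(name, ".png"))
    writeImagePNG(set@images[[i]], files[i])
  }
  manifest <- cbind(meta, file = files)
  path <- file.path(root, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
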