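#' EcgRecord: a multi-lead sampled ECG waveform
#'
#' Container for one ECG record: a samples-by-leads matrix in millivolts,
#' the sampling rate, ordered lead names, and optional diagnostic-code
#' likelihoods. Created by [generateRecord()], [readRecord()] or directly
#' via [EcgRecord()].
#'
#' @slot id Record identifier (single string).
#' @slot signals Numeric matrix, one column per lead, samples in mV.
#' @slot fs Sampling rate in Hz (positive scalar).
#' @slot leads Character vector of unique lead names, one per column.
#' @slot codes Named numeric vector mapping diagnostic codes to
#'   likelihoods (may be empty).
#' @slot components List with optional named elements `clean` and `noise`
#'   (per-lead matrices) kept by the synthetic generator so that
#'   signal-to-noise ratios can be measured against a known truth; empty
#'   for records read from disk.
#'
#' @exportClass EcgRecord
setClass("EcgRecord",
  representation(
    id = "character",
    signals = "matrix",
    fs = "numeric",
    leads = "character",
    codes = "numeric",
    components = "list"
  ),
  prototype(codes = numeric(0), components = list())
)

setValidity("EcgRecord", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a positive scalar")
  if (ncol(object@signals) != length(object@leads))
    msg <- c(msg, "number of signal columns must equal number of lead names")
  if (anyDuplicated(object@leads))
    msg <- c(msg, "lead names must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct an EcgRecord
#'
#' @param id Record identifier.
#' @param signals Numeric matrix (samples x leads) or a numeric vector for a
#'   single-lead record, in mV.
#' @param fs Sampling rate in Hz.
#' @param leads Character vector of lead names; defaults to `"v1"` for a
#'   single-lead record.
#' @param codes Named numeric vector of diagnostic-code likelihoods.
#' @param components Optional list with `clean` and `noise` matrices.
#' @return An [EcgRecord-class] object.
#' @export
EcgRecord <- function(id, signals, fs, leads = NULL, codes = numeric(0),
                      components = list()) {
  if (is.null(dim(signals))) signals <- matrix(signals, ncol = 1L)
  if (is.null(leads)) {
    leads <- if (ncol(signals) == 1L) "v1" else
      paste0("ch", seq_len(ncol(signals)))
  }
  colnames(signals) <- leads
  new("EcgRecord", id = as.character(id), signals = signals,
      fs = as.numeric(fs), leads = as.character(leads),
      codes = codes, components = components)
}

setMethod("show", "EcgRecord", function(object) {
  cat("EcgRecord '", object@id, "': ", nrow(object@signals), " samples x ",
      length(object@leads), " lead(s) @ ", object@fs, " Hz\n", sep = "")
  cat("  leads:", paste(object@leads, collapse = ", "), "\n")
  if (length(object@codes))
    cat("  codes:", paste(names(object@codes), object@codes, sep = "=",
                          collapse = ", "), "\n")
})

#' WaveletDecomposition: single-level DWT coefficients
#'
#' Approximation and detail coefficient arrays from a single-level discrete
#' wavelet transform, with the wavelet name, boundary mode and original
#' signal length needed for exact reconstruction.
#'
#' @slot approx Numeric vector of approximation (low-pass) coefficients.
#' @slot detail Numeric vector of detail (high-pass) coefficients.
#' @slot wavelet Wavelet name (only `"bior3.1"` is built in).
#' @slot mode Boundary mode (only `"periodic"` periodization is built in).
#' @slot n Original signal length before any padding.
#'
#' @exportClass WaveletDecomposition
setClass("WaveletDecomposition",
  representation(approx = "numeric", detail = "numeric",
                 wavelet = "character", mode = "character", n = "integer"))

setValidity("WaveletDecomposition", function(object) {
  msg <- character(0)
  if (object@n >= 1L && (length(object@approx) == 0L ||
                         length(object@detail) == 0L))
    msg <- c(msg, "coefficient arrays must be non-empty for non-empty input")
  expected <- ceiling(object@n / 2)
  if (length(object@approx) != expected || length(object@detail) != expected)
    msg <- c(msg, sprintf(
      "coefficient lengths (%d, %d) inconsistent with input length %d (expect %d)",
      length(object@approx), length(object@detail), object@n, expected))
  if (length(msg)) msg else TRUE
})

setMethod("show", "WaveletDecomposition", function(object) {
  cat("WaveletDecomposition (", object@wavelet, ", ", object@mode, "): ",
      length(object@approx), " approx + ", length(object@detail),
      " detail coefficients from n = ", object@n, "\n", sep = "")
})

#' SpectrogramMatrix: STFT magnitudes over sliding segments
#'
#' Non-negative matrix of short-time Fourier transform magnitudes with
#' frequency bins (two-sided, standard FFT ordering) on rows and segments
#' on columns.
#'
#' @slot mag Numeric matrix (nfft x segments) of magnitudes, all >= 0.
#' @slot freqs Numeric vector of signed bin frequencies (Hz), length nfft.
#' @slot params List of the STFT parameters used (`nfft`, `seglen`,
#'   `overlap`, `fs`, `window`).
#'
#' @exportClass SpectrogramMatrix
setClass("SpectrogramMatrix",
  representation(mag = "matrix", freqs = "numeric", params = "list"))

setValidity("SpectrogramMatrix", function(object) {
  msg <- character(0)
  if (any(object@mag < 0)) msg <- c(msg, "magnitudes must be non-negative")
  if (nrow(object@mag) != length(object@freqs))
    msg <- c(msg, "rows of 'mag' must match length of 'freqs'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SpectrogramMatrix", function(object) {
  cat("SpectrogramMatrix: ", nrow(object@mag), " frequency bins x ",
      ncol(object@mag), " segments (fs = ", object@params$fs, " Hz)\n",
      sep = "")
})

#' LabeledImageSet: grayscale images with class labels and provenance
#'
#' An ordered collection of same-shaped 8-bit grayscale images (integer
#' matrices, values 0..255) with per-item record id, binary class and
#' provenance (`original`, `flip`, `contrast` or `duplicate`).
#'
#' @slot images List of integer matrices, all the same dimension.
#' @slot meta `data.frame` with columns `id`, `class`, `provenance`,
#'   one row per image.
#'
#' @exportClass LabeledImageSet
setClass("LabeledImageSet",
  representation(images = "list", meta = "data.frame"))

setValidity("LabeledImageSet", function(object) {
  msg <- character(0)
  if (length(object@images) != nrow(object@meta))
    msg <- c(msg, "'images' and 'meta' must have the same length")
  if (!all(c("id", "class", "provenance") %in% names(object@meta)))
    msg <- c(msg, "'meta' must have columns id, class, provenance")
  if (length(object@images) > 1L) {
    d <- vapply(object@images, function(im) paste(dim(im), collapse = "x"), "")
    if (length(unique(d)) != 1L)
      msg <- c(msg, "all images must share the same dimensions")
  }
  bad <- setdiff(unique(object@meta$provenance),
                 c("original", "flip", "contrast", "duplicate"))
  if (length(bad))
    msg <- c(msg, paste("unknown provenance:", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a LabeledImageSet
#'
#' @param images List of integer grayscale matrices (0..255).
#' @param id,class Character vectors, one entry per image.
#' @param provenance Character vector per image; defaults to `"original"`.
#' @return A [LabeledImageSet-class].
#' @export
LabeledImageSet <- function(images, id, class,
                            provenance = rep("original", length(images))) {
  meta <- data.frame(id = as.character(id), class = as.character(class),
                     provenance = as.character(provenance),
                     stringsAsFactors = FALSE)
  new("LabeledImageSet", images = images, meta = meta)
}

setMethod("show", "LabeledImageSet", function(object) {
  d <- if (length(object@images)) paste(dim(object@images[[1L]]),
                                        collapse = "x") else "-"
  cat("LabeledImageSet: ", length(object@images), " images (", d, ")\n",
      sep = "")
  if (nrow(object@meta)) print(table(object@meta$class))
})

#' Number of images in a LabeledImageSet
#' @param x A [LabeledImageSet-class].
#' @export
setMethod("length", "LabeledImageSet", function(x) length(x@images))

#' Subset a LabeledImageSet
#' @param x A [LabeledImageSet-class].
#' @param i Index vector.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "LabeledImageSet", function(x, i, j, ..., drop = FALSE) {
  new("LabeledImageSet", images = x@images[i],
      meta = x@meta[i, , drop = FALSE])
})
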