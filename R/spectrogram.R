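# Short-time Fourier transform spectrograms rendered to small grayscale
# rasters. Defaults follow the pipeline settings: 9-point segments and
# FFTs, overlap floor(9/2) = 4 (segment step 5), fs 100 Hz, 64x64 output.

#' STFT parameters
#'
#' @param nfft FFT length per segment (>= `seglen`; zero-padded if longer).
#' @param seglen Segment length in samples.
#' @param overlap Samples shared by consecutive segments
#'   (`0 <= overlap < seglen`); default `floor(nfft/2)`.
#' @param fs Sampling rate in Hz.
#' @param window `"hann"` (default) or `"rect"`.
#' @return List of class `"StftParams"`.
#' @export
stftParams <- function(nfft = 9, seglen = 9, overlap = floor(nfft / 2),
                       fs = 100, window = c("hann", "rect")) {
  window <- match.arg(window)
  if (overlap < 0 || overlap >= seglen)
    stop("need 0 <= overlap < seglen")
  if (nfft < seglen) stop("nfft must be >= seglen")
  structure(list(nfft = as.integer(nfft), seglen = as.integer(seglen),
                 overlap = as.integer(overlap), fs = fs, window = window),
            class = "StftParams")
}

#' Number of STFT segments for a given input length
#'
#' `floor((L - seglen) / (seglen - overlap)) + 1`.
#'
#' @param L Input length in samples.
#' @param seglen Segment length.
#' @param overlap Overlap in samples.
#' @return Integer segment count (0 if `L < seglen`).
#' @export
countSegments <- function(L, seglen, overlap) {
  if (L < seglen) return(0L)
  as.integer((L - seglen) %/% (seglen - overlap) + 1L)
}

.windowVec <- function(window, n) {
  switch(window,
    hann = if (n == 1L) 1 else 0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / (n - 1L)),
    rect = rep(1, n))
}

#' STFT magnitude matrix
#'
#' Slides a window of `seglen` samples with step `seglen - overlap`,
#' multiplies by the window function, zero-pads each segment to `nfft`,
#' and stores the two-sided FFT magnitude of each segment as one column.
#'
#' @param x Numeric signal, at least `seglen` samples.
#' @param params An [stftParams()].
#' @return A [SpectrogramMatrix-class] (`nfft` rows, one column per
#'   segment).
#' @export
stftMatrix <- function(x, params = stftParams()) {
  L <- length(x)
  if (L < params$seglen)
    stop("input (", L, " samples) shorter than one segment (",
         params$seglen, ")")
  step <- params$seglen - params$overlap
  nseg <- countSegments(L, params$seglen, params$overlap)
  w <- .windowVec(params$window, params$seglen)
  mag <- matrix(0, nrow = params$nfft, ncol = nseg)
  for (s in seq_len(nseg)) {
    seg <- x[(s - 1L) * step + seq_len(params$seglen)] * w
    padded <- c(seg, numeric(params$nfft - params$seglen))
    mag[, s] <- Mod(fft(padded))
  }
  new("SpectrogramMatrix", mag = mag,
      freqs = fftBinFrequencies(params$nfft, params$fs),
      params = unclass(params))
}

# nearest-neighbour resize of a matrix to nr x nc
.resizeNearest <- function(m, nr, nc) {
  ri <- pmin(nrow(m), floor((seq_len(nr) - 0.5) * nrow(m) / nr) + 1L)
  ci <- pmin(ncol(m), floor((seq_len(nc) - 0.5) * ncol(m) / nc) + 1L)
  m[ri, ci, drop = FALSE]
}

# bilinear resize (optional alternative)
.resizeBilinear <- function(m, nr, nc) {
  sr <- if (nr == 1L) rep(1, nr) else seq(1, nrow(m), length.out = nr)
  sc <- if (nc == 1L) rep(1, nc) else seq(1, ncol(m), length.out = nc)
  r0 <- pmin(floor(sr), nrow(m) - 1L); r0[nrow(m) == 1L] <- 1L
  c0 <- pmin(floor(sc), ncol(m) - 1L); c0[ncol(m) == 1L] <- 1L
  fr <- sr - r0; fc <- sc - c0
  if (nrow(m) == 1L) { r0 <- rep(1L, nr); fr <- rep(0, nr) }
  if (ncol(m) == 1L) { c0 <- rep(1L, nc); fc <- rep(0, nc) }
  r1 <- pmin(r0 + 1L, nrow(m)); c1 <- pmin(c0 + 1L, ncol(m))
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    a <- m[r0, c0[j]] * (1 - fr) + m[r1, c0[j]] * fr
    b <- m[r0, c1[j]] * (1 - fr) + m[r1, c1[j]] * fr
    out[, j] <- a * (1 - fc[j]) + b * fc[j]
  }
  out
}

#' Render a spectrogram matrix as a grayscale image
#'
#' Converts magnitudes to dB (default) or leaves them linear, min-max
#' normalizes to 0..255, flips so that low frequencies sit at the bottom
#' row, and resizes to the requested square size by nearest neighbour
#' (deterministic across platforms; bilinear available). A constant-
#' magnitude matrix has no dynamic range and maps to mid-gray 128. The
#' raster carries no axes, margins or labels.
#'
#' @param sg A [SpectrogramMatrix-class].
#' @param size Output side length in pixels (default 64).
#' @param scale `"dB"` (default; `10*log10(mag^2 + 1e-12)`) or `"linear"`.
#' @param interp `"nearest"` (default) or `"bilinear"`.
#' @return Integer matrix `size x size`, values in 0..255.
#' @export
renderSpectrogram <- function(sg, size = 64, scale = c("dB", "linear"),
                              interp = c("nearest", "bilinear")) {
  scale <- match.arg(scale)
  interp <- match.arg(interp)
  m <- sg@mag
  if (!length(m)) stop("empty spectrogram matrix")
  if (scale == "dB") m <- 10 * log10(m^2 + 1e-12)
  # reorder rows: negative bins first, then positives descending, so that
  # the lowest frequency is the bottom row of the image
  ord <- order(sg@freqs, decreasing = TRUE)
  m <- m[ord, , drop = FALSE]
  rng <- range(m)
  norm <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else
    matrix(128 / 255, nrow(m), ncol(m))
  img <- if (interp == "nearest") .resizeNearest(norm, size, size) else
    .resizeBilinear(norm, size, size)
  mode(img) <- "numeric"
  matrix(as.integer(pmin(pmax(round(img * 255), 0), 255)), size, size)
}

#' Render a raw signal as a grayscale line plot raster
#'
#' Rasterizes the amplitude-versus-sample-index polyline into a square
#' grayscale grid: dark line (0) on a light background (255), no axes or
#' margins. The value-to-row mapping is exactly mirror-symmetric, so
#' rendering `-x` gives the vertical mirror of rendering `x`. A constant
#' series (zero range) draws a 2-pixel horizontal line across the middle.
#'
#' @param x Numeric series (non-empty).
#' @param size Output side length in pixels (default 64).
#' @return Integer matrix `size x size`, values 0 or 255.
#' @export
renderRawSignal <- function(x, size = 64) {
  if (!length(x)) stop("cannot render an empty series")
  img <- matrix(255L, size, size)
  L <- length(x)
  rng <- range(x)
  if (rng[2] == rng[1]) {
    mid <- size %/% 2L
    img[c(mid, mid + 1L), ] <- 0L
    return(img)
  }
  ypix <- (size - 1) * (rng[2] - x) / (rng[2] - rng[1])  # 0 = top row
  if (L == 1L) {
    rows <- floor(ypix[1L]):ceiling(ypix[1L])
    img[rows + 1L, ] <- 0L
    return(img)
  }
  tAt <- function(c) c * (L - 1) / (size - 1)   # column -> sample position
  interpY <- function(tt) {
    i0 <- pmin(floor(tt), L - 2L)
    fr <- tt - i0
    ypix[i0 + 1L] * (1 - fr) + ypix[i0 + 2L] * fr
  }
  for (cc in seq_len(size) - 1L) {
    t0 <- tAt(max(cc - 0.5, 0))
    t1 <- tAt(min(cc + 0.5, size - 1))
    inner <- seq_len(L) - 1L
    inner <- inner[inner > t0 & inner < t1]
    ys <- c(interpY(t0), interpY(t1), ypix[inner + 1L])
    r0 <- max(0L, floor(min(ys)))
    r1 <- min(size - 1L, ceiling(max(ys)))
    img[(r0:r1) + 1L, cc + 1L] <- 0L
  }
  img
}

#' Write a grayscale image matrix as an 8-bit PNG
#'
#' @param img Integer matrix with values 0..255.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeImagePNG <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}
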